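type: suspension
name: exp1_92uM
cell_volume_fraction: 0.022
glc_added: 92.0
duration: 300.0
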