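type: suspension
name: exp2_776uM
cell_volume_fraction: 0.029
glc_added: 776.0
duration: 300.0
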