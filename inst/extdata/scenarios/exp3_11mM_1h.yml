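type: suspension
name: exp3_11mM_1h
cell_volume_fraction: 0.022
glc_added: 11100.0
duration: 3600.0
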