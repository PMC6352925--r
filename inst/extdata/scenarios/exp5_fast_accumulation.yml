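type: suspension
name: exp5_fast_accumulation
cell_volume_fraction: 0.029
glc_added: 77.0
duration: 60.0
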