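type: suspension
name: exp7_pyruvate
cell_volume_fraction: 0.029
glc_added: 10000.0
pyr_added: 5000.0
duration: 300.0
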