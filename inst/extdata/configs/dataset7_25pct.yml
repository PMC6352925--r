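type: ascites
n_layers: 63
layer_width: 10.0
geometry: radial
vessel_radius: 10.0
cell_volume_fraction: 0.25
steady_state: yes
duration: 180.0
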