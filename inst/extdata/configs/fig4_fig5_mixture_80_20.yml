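type: tissue
glc_in: 13000.0
n_layers: 8
layer_width: 5.0
flow_offset: 4.4
flow_amplitude: 4.4
flow_period: 100.0
mixture:
- share: 0.8
  capacity: 1.0
- share: 0.2
  capacity: 0.1
report_layer: 4
duration: 2000.0
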