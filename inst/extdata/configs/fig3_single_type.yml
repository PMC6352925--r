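type: tissue
glc_in: 13000.0
n_layers: 8
layer_width: 5.0
flow_offset: 4.4
flow_amplitude: 4.4
flow_period: 100.0
mixture:
- share: 1.0
  capacity: 1.0
interventions:
- type: uncouple_fbp_buffer
  t_start: 3505.0
  t_end: 3550.0
report_layer: 4
duration: 3700.0
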