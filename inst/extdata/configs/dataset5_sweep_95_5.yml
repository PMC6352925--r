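type: tissue
glc_in: 13000.0
n_layers: 8
layer_width: 5.0
flow_offset: 2.2
flow_amplitude: 3.5
flow_period: 420.0
mixture:
- share: 0.95
  capacity: 1.0
- share: 0.05
  capacity: 0.1
param_overrides:
  hyd_max: 100.0
  hyd_pool_slope: 0.02
report_layer: 8
duration: 2400.0
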