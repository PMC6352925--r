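type: suspension
name: exp4_dose_response
cell_volume_fraction: 0.022
glc_added: 0.0
duration: 120.0
doses: [25.0, 50.0, 92.0, 200.0, 400.0, 776.0]
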