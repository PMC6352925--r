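# Calibrated kinetic parameters for Ehrlich ascites tumor cells.
# Units: concentrations uM (umol per liter intracellular water),
# fluxes uM/s; head-section fluxes in 6-carbon, tail in 3-carbon units.
vmax_head: 337.0
km_glc_head: 51.0
km_atp_head: 200.0
head_form: 1
vmax_tail: 2915.77
km_fbp_tail: 118.585
km_nad_tail: 150.0
km_adp_tail: 606.749
km_pi_tail: 1000.0
ki_nadh_tail: 42.0
vmax_oxphos: 400.0
km_adp_ox: 80.0
km_pi_ox: 400.0
km_o2_ox: 1.0
km_nadh_ox: 0.2
km_pyr_ox: 2.0
p_over_o: 2.5
vf_ldh: 1550.0
km_pyr_ldh: 200.0
km_nadh_ldh: 2.0
km_lac_ldh: 17000.0
km_nad_ldh: 849.0
keq_ldh: 16200.0
hyd_max: 177.0
hyd_pool_slope: 0.0884175
km_atp_hyd: 100.0
k_pool_loss: 1.01252
adp_threshold: 143.136
k_resyn: 4.41857e-04
k_inact: 1.3e-05
k_react: 4.5e-03
r_pgi: 1.24
k_sink: 6.8e-03
nad_total: 1000.0
a_pool_init: 3000.0
atp_init: 2600.0
pi_init: 3000.0
water_frac: 0.7
glycolytic_capacity_scale: 1.0
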