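# Shared fixtures: the packaged EATC parameter set and small cached
# simulations reused across test files (built once per test run).
p_eatc <- cell_parameters()

# a light 776 µM glucose-addition run reused by several tests
sim_776 <- local({
  scn <- suspension_scenario(0.029, glc_added = 776, duration = 300,
                             name = "test_776")
  run_suspension(scn, p_eatc)
})

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
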