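test_that("head flux vanishes without substrate or active enzyme and is bounded", {
  p <- p_eatc
  expect_equal(head_flux(0, 2000, 1, p), 0)
  expect_equal(head_flux(5000, 2000, 0, p), 0)
  expect_equal(head_flux(5000, 0, 1, p), 0)
  # bounded by f_active * vmax * capacity
  expect_lt(head_flux(1e9, 1e9, 0.5, p),
            0.5 * p$vmax_head * p$glycolytic_capacity_scale + 1e-9)
})

test_that("head flux is half-maximal at km_glc_head when ATP saturates", {
  p <- p_eatc
  atp <- 1e9
  ratio <- head_flux(p$km_glc_head, atp, 1, p) /
    head_flux(1e6, atp, 1, p)
  # expected ratio of the Michaelis form itself
  expected <- 0.5 / (1e6 / (1e6 + p$km_glc_head))
  expect_equal(ratio, expected, tolerance = 1e-9)
  expect_equal(p$km_glc_head, 51)
})

test_that("head flux is monotone in each argument", {
  p <- p_eatc
  glc <- c(10, 50, 200, 1000, 10000)
  expect_true(all(diff(head_flux(glc, 2000, 1, p)) > 0))
  atp <- c(100, 500, 1000, 3000)
  expect_true(all(diff(head_flux(500, atp, 1, p)) > 0))
  f <- c(0.1, 0.4, 0.9)
  expect_true(all(diff(head_flux(500, 2000, f, p)) > 0))
  # both head formulations agree on the limiting behaviour
  p2 <- cell_parameters(head_form = 2)
  expect_equal(head_flux(0, 2000, 1, p2), 0)
  expect_true(all(diff(head_flux(glc, 2000, 1, p2)) > 0))
})

test_that("head flux rejects invalid inputs naming the argument", {
  expect_error(head_flux(-1, 2000, 1, p_eatc), "glc")
  expect_error(head_flux(100, -5, 1, p_eatc), "atp")
  expect_error(head_flux(100, 5, 1.4, p_eatc), "f_active")
})

test_that("tail flux honours substrate and redox limits", {
  p <- p_eatc
  expect_equal(tail_flux(0, 50, 500, 3000, p), 0)
  expect_equal(tail_flux(2000, p$nad_total, 500, 3000, p), 0)
  expect_equal(tail_flux(2000, 50, 0, 3000, p), 0)
  expect_equal(tail_flux(2000, 50, 500, 0, p), 0)
  # NADH inhibition: more NADH, less flux
  expect_lt(tail_flux(2000, 0.9 * p$nad_total, 500, 3000, p),
            tail_flux(2000, 0.1 * p$nad_total, 500, 3000, p))
  expect_error(tail_flux(2000, p$nad_total + 5, 500, 3000, p),
               "nad_total")
  expect_lt(tail_flux(1e9, 0, 1e9, 1e9, p),
            p$vmax_tail * p$glycolytic_capacity_scale + 1e-9)
})

test_that("oxidative phosphorylation couples ATP and O2 stoichiometrically", {
  p <- p_eatc
  expect_equal(oxphos_flux(50, 3000, 0, p)$j_atp, 0)
  expect_equal(oxphos_flux(0, 3000, 30, p)$j_atp, 0)
  fx <- oxphos_flux(50, 3000, 30, p, nadh = 40, pyr = 30)
  expect_equal(fx$j_o2 * 2 * p$p_over_o, fx$j_atp)
  expect_gt(fx$j_atp, 0)
  expect_lt(fx$j_atp, p$vmax_oxphos)
})

test_that("LDH flux is reversible with the correct equilibrium", {
  p <- p_eatc
  # equilibrium: pyr * nadh = lac * nad / keq
  nadh <- 10
  nad <- p$nad_total - nadh
  lac <- 4000
  pyr <- lac * nad / (p$keq_ldh * nadh)
  expect_equal(ldh_flux(pyr, nadh, lac, p), 0, tolerance = 1e-10)
  # lactate consumed when glucose-derived pyruvate is absent
  expect_lt(ldh_flux(0, 5, 5000, p), 0)
  expect_equal(ldh_flux(0, 0, 0, p), 0)
  # net production when pyruvate and NADH are abundant
  expect_gt(ldh_flux(500, 200, 1000, p), 0)
})

test_that("ATP hydrolysis tracks the adenine pool linearly with clamping", {
  p <- p_eatc
  expect_equal(atp_hydrolysis_flux(p$a_pool_init, p), p$hyd_max)
  deficit_zero <- p$a_pool_init - p$hyd_max / p$hyd_pool_slope
  expect_equal(atp_hydrolysis_flux(max(deficit_zero, 0), p), 0)
  half <- p$a_pool_init - 0.5 * p$hyd_max / p$hyd_pool_slope
  expect_equal(atp_hydrolysis_flux(half, p), p$hyd_max / 2)
  expect_error(atp_hydrolysis_flux(p$a_pool_init + 10, p),
               "a_pool")
})

test_that("feedback kinetics have the algebraic fixed point", {
  p <- p_eatc
  expect_equal(feedback_rate(1, 0, p), 0)
  expect_equal(feedback_rate(0, 12345, p), p$k_react)
  pgi <- 2000
  f_star <- p$k_react / (p$k_react + p$k_inact * pgi)
  expect_equal(feedback_rate(f_star, pgi, p), 0, tolerance = 1e-12)
  # long-time integration converges to the same fixed point
  out <- deSolve::lsoda(c(f = 0.99), c(0, 5e4),
                        function(t, y, parms)
                          list(feedback_rate(min(y, 1), pgi, p)),
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_equal(unname(out[nrow(out), 2]), f_star, tolerance = 1e-10)
})

test_that("total PGI pool is linear in FBP with the packaged ratio", {
  p <- p_eatc
  expect_equal(pgi_total(0, p), 0)
  p2 <- cell_parameters(r_pgi = 1.24)
  expect_equal(pgi_total(5000, p2), 6200)
  fbp <- c(10, 100, 1000)
  expect_equal(pgi_total(fbp, p), p$r_pgi * fbp)
})
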