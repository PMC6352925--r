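# small fast scenario shared by the calibration tests
cal_scn <- list(fast = suspension_scenario(
  0.029, glc_added = 400, duration = 60, spinup = 1500,
  sampling = seq(0, 60, 1), name = "fast"))

test_that("noise-free synthetic tables equal the model output exactly", {
  tab <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0,
                                    seed = 7, times = c(5, 20, 40))
  expect_equal(tab$value, tab$true_value)
  sim <- run_suspension(cal_scn$fast, p_eatc)
  fbp5 <- tab$value[tab$observable == "fbp" & tab$time == 5]
  expect_equal(fbp5, approx(sim$time, sim$fbp, 5)$y)
})

test_that("synthetic tables are reproducible under a fixed seed", {
  a <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0.05,
                                  seed = 11, times = c(5, 30))
  b <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0.05,
                                  seed = 11, times = c(5, 30))
  expect_identical(a$value, b$value)
  c <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0.05,
                                  seed = 12, times = c(5, 30))
  expect_false(identical(a$value, c$value))
})

test_that("replicate scatter matches the requested noise level", {
  tab <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0.05,
                                    seed = 3, times = c(10, 30),
                                    n_replicates = 60,
                                    observables = "fbp")
  rel_sd <- tapply(tab$value / tab$true_value, tab$time, sd)
  # sd of 60 draws at sigma = 0.05: well within 3x sampling error
  expect_true(all(abs(rel_sd - 0.05) < 3 * 0.05 / sqrt(2 * 59)))
})

test_that("an empty free list returns the initial parameters with the plain objective", {
  tab <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0,
                                    seed = 1, times = c(5, 20, 40))
  fit <- fit_parameters(tab, cal_scn, p_eatc, free = character(0))
  expect_identical(unclass(fit$params), unclass(p_eatc))
  expect_lt(fit$objective, 1e-12)
})

test_that("noiseless single-parameter perturbations are recovered to 1%", {
  tab <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0,
                                    seed = 1,
                                    times = c(2, 5, 10, 20, 40, 60))
  for (nm in c("vmax_head", "vmax_tail")) {
    p0 <- cell_parameters()
    p0[[nm]] <- p0[[nm]] * 2
    p0 <- glycodyn:::validate_cell_parameters(p0)
    fit <- fit_parameters(tab, cal_scn, p0, free = nm, n_starts = 1,
                          maxit = 80)
    expect_equal(fit$params[[nm]], p_eatc[[nm]],
                 tolerance = 0.01)
  }
})

test_that("a parameter with no effect on the data is flagged as non-identifiable", {
  # under anoxia oxidative phosphorylation is off, so its O2 affinity
  # cannot be informed by the data
  anox <- list(anox = suspension_scenario(
    0.029, glc_added = 400, duration = 40, o2_mode = "anoxic",
    sampling = seq(0, 40, 2), name = "anox"))
  tab <- generate_synthetic_dataset(p_eatc, anox, noise = 0,
                                    seed = 1, times = c(5, 20),
                                    observables = "fbp")
  expect_warning(
    fit <- fit_parameters(tab, anox, p_eatc, free = "km_o2_ox",
                          n_starts = 1, maxit = 10),
    "non-identifiable")
  expect_true("km_o2_ox" %in% fit$flat)
})

test_that("uncertainty bands collapse for one draw and for noiseless data", {
  tab <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0,
                                    seed = 1, times = c(5, 20, 40))
  fit <- fit_parameters(tab, cal_scn, p_eatc, free = "vmax_head",
                        n_starts = 1, maxit = 20)
  uq1 <- uncertainty_ensemble(fit, n_draws = 1, seed = 2)
  expect_equal(uq1$bands$lo, uq1$bands$hi)
  uq0 <- uncertainty_ensemble(fit, n_draws = 30, seed = 2,
                              method = "laplace")
  # noiseless residuals: near-zero-width bands
  width <- uq0$bands$hi - uq0$bands$lo
  expect_true(all(width / pmax(abs(uq0$bands$fit), 1) < 1e-3))
})

test_that("bands widen with measurement noise and tidiers report the fit", {
  noisy <- generate_synthetic_dataset(p_eatc, cal_scn, noise = 0.05,
                                      seed = 5, times = c(5, 20, 40))
  fit <- fit_parameters(noisy, cal_scn, p_eatc, free = "vmax_head",
                        n_starts = 1, maxit = 30)
  uq <- uncertainty_ensemble(fit, n_draws = 30, seed = 2,
                             method = "laplace")
  expect_gt(mean(uq$bands$hi - uq$bands$lo), 0)
  td <- tidy(fit)
  expect_equal(td$term, "vmax_head")
  expect_true(td$identifiable)
  g <- glance(fit)
  expect_equal(g$n_free, 1)
})
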