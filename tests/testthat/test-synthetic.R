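test_that("zero-noise simulation is identical to direct evaluation", {
  caf <- caf_params()
  sim <- simulate_trace(caf, 0.51, std_times())
  ref <- eval_trace(caf, 0.51, std_times())
  expect_identical(sim$signal, ref$signal)
  expect_true(sim$calibrated)
})

test_that("noisy generation is deterministic given the seed", {
  caf <- caf_params()
  n <- trace_noise(multiplicative_sd = 0.02, additive_sd = 0.5, seed = 31)
  a <- simulate_trace(caf, 0.51, std_times(), n)
  b <- simulate_trace(caf, 0.51, std_times(), n)
  expect_identical(a$signal, b$signal)
  c_ <- simulate_trace(caf, 0.51, std_times(),
                       trace_noise(multiplicative_sd = 0.02,
                                   additive_sd = 0.5, seed = 32))
  expect_false(identical(a$signal, c_$signal))
  expect_error(trace_noise(multiplicative_sd = 0.02), "seed")
  expect_error(trace_noise(additive_sd = -1), ">= 0")
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(simulate_trace(caf_params(), 0.51, std_times(),
                           trace_noise(multiplicative_sd = 0.02, seed = 7)))
  expect_identical(runif(1), before)
})

test_that("baseline drift adds a linear term in hours", {
  caf <- caf_params()
  drifted <- simulate_trace(caf, 0.51, std_times(),
                            trace_noise(baseline_drift = 0.6))
  clean <- eval_trace(caf, 0.51, std_times())
  expect_equal(drifted$signal - clean$signal, 0.6 * std_times() / 3600,
               tolerance = 1e-12)
})

test_that("mucin series generator encodes viscosity and binding effects", {
  times <- seq(120, 64800, by = 480)
  conc <- c(0, 0.1, 0.3, 0.6)
  # slope chosen so that D(0.6%) = 0.37 * D_0 (63% reduction)
  sim <- simulate_mucin_series(5.81e-6, 648, 0.11, 0.51, times, conc,
                               effect = mucin_effect(viscosity_slope = 1.05))
  expect_equal(sim$truth$D[4] / sim$truth$D[1], 0.37, tolerance = 1e-10)
  res <- fit_diffusivity_series(sim$traces, x_m = 0.51)
  tab <- reduction_table(res$series)
  expect_equal(tab$reduction_pct[4], 63, tolerance = 0.01)
  # with all effects zero the series is flat and reductions vanish
  flat <- simulate_mucin_series(5.81e-6, 648, 0.11, 0.51, times, conc)
  expect_equal(unique(flat$truth$D), 5.81e-6)
  expect_error(
    simulate_mucin_series(5.81e-6, 648, 0.11, 0.51, times, conc,
                          effect = mucin_effect(viscosity_slope = 2)),
    "zero or below")
  expect_error(
    simulate_mucin_series(5.81e-6, 648, 0.11, 0.51, times, c(0.1, 0.3)),
    "include 0")
})

test_that("bound drug reduces the fitted amount, not the diffusivity", {
  times <- seq(120, 64800, by = 480)
  # 30% bound at the top concentration: bound_slope * 0.6 = 0.3
  sim <- simulate_mucin_series(9.07e-6, 111, 0.11, 0.51, times, c(0, 0.6),
                               effect = mucin_effect(bound_slope = 0.5))
  res <- fit_diffusivity_series(sim$traces, x_m = 0.51)
  mb_water <- mass_balance(res$table$A[1], default_geometry(), C_n = 0.86)
  mb_mucin <- mass_balance(res$table$A[2], default_geometry(), C_n = 0.86)
  expect_equal(mb_mucin$ratio / mb_water$ratio, 0.7, tolerance = 1e-4)
  expect_equal(res$table$D[2], res$table$D[1], tolerance = 1e-6)
})

test_that("permeation generator respects sink conditions and the seed", {
  template <- permeation_experiment(default_sampling_times(), rep(0, 8),
                                    C_d = 1000, V_donor = 2000)
  zero <- simulate_permeation(0, template)
  expect_equal(zero$acceptor_concentrations, rep(0, 8))
  a <- simulate_permeation(5e-6, template, noise_sd = 0.05, seed = 3)
  b <- simulate_permeation(5e-6, template, noise_sd = 0.05, seed = 3)
  expect_identical(a$acceptor_concentrations, b$acceptor_concentrations)
  expect_error(simulate_permeation(5e-6, template, noise_sd = 0.05), "seed")
  # the default 100 uL donor cannot sustain this flux under sink conditions
  small_donor <- permeation_experiment(default_sampling_times(), rep(0, 8),
                                       C_d = 1000, V_donor = 100)
  expect_error(simulate_permeation(9.09e-6, small_donor), "sink")
})
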