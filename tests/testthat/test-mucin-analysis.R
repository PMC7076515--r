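test_that("percentage reduction follows 100*(1 - D_rel/D_0)", {
  expect_equal(percent_reduction(9.07e-6, 6.0769e-6), 33.0, tolerance = 1e-3)
  expect_equal(percent_reduction(5.81e-6, 2.1497e-6), 63.0, tolerance = 1e-3)
  expect_equal(percent_reduction(4e-6, 4e-6), 0)
  expect_warning(r <- percent_reduction(4e-6, 5e-6), "negative reduction")
  expect_lt(r, 0)
  expect_error(percent_reduction(0, 1e-6), "positive")
})

test_that("percent reduction is antitone in D_rel", {
  D_rel <- seq(1e-6, 9e-6, length.out = 20)
  red <- percent_reduction(9.07e-6, D_rel)
  expect_true(all(diff(red) < 0))
})

test_that("reduction table round-trips the reference reduction rows", {
  refs <- reference_reductions()
  drugs <- reference_drugs()
  for (drug in c("ATN", "CAF", "HYD", "NPR")) {
    D_0 <- drugs$D_0[drugs$drug == drug]
    series <- apply_reductions(D_0, refs$mucin_pct, refs[[drug]])
    tab <- reduction_table(series)
    expect_equal(tab$reduction_pct, refs[[drug]], tolerance = 1e-10)
    expect_equal(tab$reduction_pct[1], 0)
  }
  const <- mucin_series(c(0, 0.1, 0.3), rep(5e-6, 3))
  expect_equal(reduction_table(const)$reduction_pct, c(0, 0, 0))
  no_base <- mucin_series(c(0.1, 0.3), c(5e-6, 4e-6))
  expect_error(reduction_table(no_base), "baseline")
})

test_that("mucin self-diffusion series is consistent with its reductions", {
  # D = 3.1e-6 at 0.1% with a 14% reduction implies the water baseline;
  # applying the 39% reduction at 0.6% lands near 2.2e-6
  D_0 <- 3.1e-6 / (1 - 0.14)
  s <- apply_reductions(D_0, c(0, 0.1, 0.6), c(0, 14, 39))
  expect_equal(s$D_values[2], 3.1e-6, tolerance = 1e-10)
  expect_equal(s$D_values[3], 2.2e-6, tolerance = 0.025)
})

test_that("inverse-diffusivity linearity reproduces the known R2 values", {
  refs <- reference_reductions()
  atn <- apply_reductions(5.81e-6, refs$mucin_pct, refs$ATN)
  expect_equal(inverse_D_regression(atn)$r2, 0.9993437, tolerance = 1e-6)
  npr <- apply_reductions(8.02e-6, refs$mucin_pct, refs$NPR)
  expect_equal(inverse_D_regression(npr)$r2, 0.9867314, tolerance = 1e-6)
  # exactly collinear 1/D gives R2 = 1
  conc <- c(0, 0.1, 0.3, 0.6)
  lin <- mucin_series(conc, 1 / (1e5 + 2e5 * conc))
  expect_equal(inverse_D_regression(lin)$r2, 1, tolerance = 1e-12)
  expect_error(inverse_D_regression(mucin_series(c(0, 0.1), c(2e-6, 1e-6))),
               "at least 3")
})

test_that("mass balance compares fitted against injected amount", {
  mb <- mass_balance(111, default_geometry(), C_n = 0.86)
  expect_equal(mb$n_dif, 22.2)
  expect_equal(mb$n_i, 21.5)
  expect_equal(mb$ratio, 22.2 / 21.5, tolerance = 1e-12)
  expect_equal(mass_balance(0, default_geometry(), 1)$ratio, 0)
})

test_that("fitted amount is linear in nominal concentration, slope Vi/S", {
  drugs <- reference_drugs()
  res <- amount_vs_concentration_regression(drugs$C_n, drugs$A_0,
                                            default_geometry())
  expect_gt(res$r2, 0.998)
  expect_equal(res$slope_theoretical, 125)
  # exact pairs on the theoretical slope recover it with R2 = 1
  C_n <- c(0.5, 1, 2, 4)
  exact <- amount_vs_concentration_regression(C_n, 125 * C_n,
                                              default_geometry())
  expect_equal(exact$slope, 125, tolerance = 1e-10)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_error(
    amount_vs_concentration_regression(rep(1, 3), c(1, 2, 3),
                                       default_geometry()),
    "degenerate")
})

test_that("Stokes-Einstein conversion gives sub-nm radii for small drugs", {
  r <- stokes_einstein_radius(9.07e-6)
  expect_equal(r, 0.2705326, tolerance = 1e-6)
  # inverse proportionality and exact round-trip
  expect_equal(stokes_einstein_radius(9.07e-6 / 2), 2 * r, tolerance = 1e-12)
  for (D in c(1e-6, 5.81e-6, 9.07e-6, 2e-5)) {
    expect_equal(stokes_einstein_D(stokes_einstein_radius(D)), D,
                 tolerance = 1e-12)
  }
  expect_error(stokes_einstein_radius(-1e-6), "positive")
})

test_that("diffusivity-radius regression behaves on exact and noisy panels", {
  cons <- physical_constants()
  r <- seq(0.2, 1.2, length.out = 14)
  D <- stokes_einstein_D(r, cons)
  exact <- diffusivity_radius_regression(D, 1 / r)
  expect_equal(exact$r2, 1, tolerance = 1e-10)
  # 10% radius noise: correlation degrades but is reproducible under a seed
  set.seed(99)
  r_noisy <- r * (1 + rnorm(14, 0, 0.10))
  noisy <- diffusivity_radius_regression(D, 1 / r_noisy)
  expect_lt(noisy$r2, 1)
  expect_gt(noisy$r2, 0.5)
  set.seed(99)
  r_again <- r * (1 + rnorm(14, 0, 0.10))
  expect_identical(diffusivity_radius_regression(D, 1 / r_again)$r2,
                   noisy$r2)
  expect_error(diffusivity_radius_regression(D[1:2], 1 / r[1:2]),
               "at least 3")
})

test_that("mucin series validates its invariants", {
  expect_error(mucin_series(c(0, 0.1), c(1e-6)), "same length")
  expect_error(mucin_series(c(0, 0), c(1e-6, 2e-6)), "unique")
  expect_error(mucin_series(c(0, -0.1), c(1e-6, 2e-6)), "nonnegative")
  expect_error(mucin_series(c(0, 0.1), c(1e-6, 0)), "positive")
  s <- mucin_series(c(0.3, 0, 0.1), c(3e-6, 5e-6, 4e-6))
  expect_equal(s$concentrations, c(0, 0.1, 0.3))   # sorted on construction
  expect_equal(s$D_values, c(5e-6, 4e-6, 3e-6))
})
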