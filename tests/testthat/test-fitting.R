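test_that("initial guess inverts the peak relations", {
  caf <- caf_params()
  tr <- eval_trace(caf, 0.51, std_times())
  g <- initial_guess(tr)
  expect_equal(g$D, 9.07e-6, tolerance = 0.20)
  expect_equal(g$A, 111, tolerance = 0.25)
  # a trace peaking at 21343 s implies D ~ 5.86e-6 with the default sigma0
  slow <- eval_trace(diffusion_params(648, 0.1, 5.859e-6), 0.51, std_times())
  g2 <- initial_guess(slow)
  expect_equal(g2$D, (0.51^2 - 0.1^2) / (2 * 21343), tolerance = 0.02)
  # degenerate monotone trace falls back to defaults with a warning
  flat <- diffusion_trace(std_times(), rep(1, 540) + 1e-9 * seq_len(540),
                          x_m = 0.51)
  expect_warning(g3 <- initial_guess(flat), "no interior maximum")
  expect_equal(g3$D, 5e-6)
})

test_that("noiseless traces are recovered within 1% from perturbed starts", {
  caf <- caf_params()
  tr <- eval_trace(caf, 0.51, std_times())
  set.seed(101)
  for (rep in 1:5) {
    start <- diffusion_params(caf$A * runif(1, 0.5, 1.5),
                              caf$sigma * runif(1, 0.5, 1.5),
                              caf$D * runif(1, 0.5, 1.5))
    fit <- fit_diffusion(tr, start = start)
    expect_true(fit$converged)
    expect_equal(fit$params$A, caf$A, tolerance = 0.01)
    expect_equal(fit$params$sigma, caf$sigma, tolerance = 0.01)
    expect_equal(fit$params$D, caf$D, tolerance = 0.01)
    expect_lt(fit$fit_error_pct, 1)
  }
})

test_that("sigma and D are invariant to signal rescaling; A scales", {
  caf <- caf_params()
  tr <- eval_trace(caf, 0.51, std_times())
  scaled <- diffusion_trace(tr$times, tr$signal * 3.7, x_m = 0.51)
  f1 <- fit_diffusion(tr)
  f2 <- fit_diffusion(scaled)
  expect_equal(f2$params$sigma, f1$params$sigma, tolerance = 1e-6)
  expect_equal(f2$params$D, f1$params$D, tolerance = 1e-6)
  expect_equal(f2$params$A, 3.7 * f1$params$A, tolerance = 1e-6)
})

test_that("replicate spread under noise is consistent with reported SEs", {
  caf <- caf_params()
  fits <- lapply(1:20, function(s) {
    tr <- simulate_trace(caf, 0.51, std_times(),
                         trace_noise(multiplicative_sd = 0.02, seed = s))
    fit_diffusion(tr)
  })
  D_hat <- vapply(fits, function(f) f$params$D, numeric(1))
  se_D <- vapply(fits, function(f) f$std_errors[["D"]], numeric(1))
  ratio <- stats::sd(D_hat) / stats::median(se_D)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("degenerate inputs are rejected, non-convergence is never silent", {
  short <- eval_trace(caf_params(), 0.51, seq(120, 600, 120))
  expect_error(fit_diffusion(short), "at least 10")
  const <- diffusion_trace(std_times(), rep(2, 540), x_m = 0.51)
  expect_error(fit_diffusion(const), "constant")
})

test_that("per-concentration series fits preserve a monotone truth", {
  times <- seq(120, 64800, by = 480)
  sim <- simulate_mucin_series(
    D_0 = 9.07e-6, A_0 = 111, sigma = 0.11, x_m = 0.51, times = times,
    concentrations = c(0, 0.1, 0.3, 0.6),
    effect = mucin_effect(viscosity_slope = 1.05))
  res <- fit_diffusivity_series(sim$traces, x_m = 0.51)
  expect_equal(res$table$D, sim$truth$D, tolerance = 1e-4)
  expect_true(all(diff(res$table$D) < 0))
  # baseline concentration is mandatory, duplicate keys are rejected
  expect_error(fit_diffusivity_series(sim$traces[-1], x_m = 0.51),
               "concentration 0")
  dup <- sim$traces[c(1, 1, 2)]
  expect_error(fit_diffusivity_series(dup, x_m = 0.51), "duplicate")
  single <- fit_diffusivity_series(sim$traces[1], x_m = 0.51)
  expect_length(single$fits, 1L)
})

test_that("fick_fit supports the standard modelling methods", {
  caf <- caf_params()
  tr <- eval_trace(caf, 0.51, std_times())
  fit <- fit_diffusion(tr)
  expect_named(coef(fit), c("A", "sigma", "D"))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_length(residuals(fit), fit$n_used)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(predict(fit, times = 13671.44),
               fick_concentration(caf, 0.51, 13671.44), tolerance = 1e-8)
  expect_output(print(fit), "D ")
  expect_output(print(summary(fit)), "R\\^2")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  sims <- simulate(fit, nsim = 2, seed = 11)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "diffusion_trace")
  expect_error(simulate(fit, nsim = 1), "seed")
})
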