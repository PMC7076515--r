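#' Initial parameter guess from a measured trace
#'
#' Inverts the closed-form peak relations: with a default layer width
#' `sigma0`, the observed peak time gives
#' `D0 = (x_m^2 - sigma0^2) / (2 t_peak)` and the observed peak height gives
#' `A0` through `c_max = (2A/sqrt(pi)) exp(-1/2) / (x_m sqrt(2))` (the trace
#' maximum of the model when `sigma << x_m`).  A trace without an interior
#' maximum (monotone, flat, or peaked at the boundary) falls back to the
#' configured defaults with a warning.
#'
#' @param trace A [diffusion_trace()].
#' @param x_m Observation height, cm; defaults to `trace$x_m`.
#' @param sigma0 Default width guess, cm.
#' @param defaults Fallback [diffusion_params()] used for degenerate traces.
#'
#' @return A [diffusion_params()] object.
#' @export
initial_guess <- function(trace, x_m = trace$x_m, sigma0 = 0.1,
                          defaults = diffusion_params(A = 100, sigma = sigma0,
                                                      D = 5e-6)) {
  stopifnot(inherits(trace, "diffusion_trace"))
  i_max <- which.max(trace$signal)
  interior <- i_max > 1L && i_max < length(trace$signal) &&
    stats::sd(trace$signal) > 0 && x_m > sigma0
  if (!interior) {
    warning("trace has no interior maximum; using default initial guess")
    return(defaults)
  }
  t_peak <- trace$times[i_max]
  D0 <- (x_m^2 - sigma0^2) / (2 * t_peak)
  c_max <- trace$signal[i_max]
  A0 <- c_max * x_m * sqrt(2) * sqrt(pi) / (2 * exp(-0.5))
  diffusion_params(A = A0, sigma = sigma0, D = D0)
}

#' Fit the closed-form diffusion model to a time trace
#'
#' Estimates the parameter triple (`A`, `sigma`, `D`) by bounded nonlinear
#' least squares (Levenberg-Marquardt) on
#' `signal_i ~ c(x_m, t_i; A, sigma, D)`.  Standard errors come from the
#' Jacobian-based linearised covariance; the relative standard error of `D`
#' (in percent) is reported as `fit_error_pct`, the conventional fitting
#' precision for this method.
#'
#' Points with `t < burn_in` are discarded (the first sampling interval is
#' typically contaminated by the injection transient).
#'
#' @param trace A [diffusion_trace()].
#' @param x_m Observation height, cm; defaults to `trace$x_m`.
#' @param start Optional [diffusion_params()] starting values; defaults to
#'   [initial_guess()].
#' @param lower,upper Named bounds for `A`, `sigma` (cm) and `D` (cm^2/s).
#'   Defaults bracket all small-molecule aqueous diffusivities and the
#'   cuvette scale: `D` in `[1e-8, 1e-3]`, `sigma` in `[0.01, 1.0]`.
#' @param burn_in Discard samples earlier than this time, s (default 120).
#' @param maxiter Maximum optimizer iterations.
#'
#' @return An object of class `fick_fit` with components `params`
#'   ([diffusion_params()]), `std_errors`, `fit_error_pct`, `rmse`, `r2`,
#'   `n_used`, `converged`, plus the data actually fitted and the underlying
#'   `nls` object.  Supports `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `residuals`, `fitted`, `plot` and `simulate`.
#' @export
#'
#' @examples
#' caf <- diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)
#' tr <- eval_trace(caf, x_m = 0.51, times = seq(120, 64800, by = 120))
#' fit <- fit_diffusion(tr)
#' coef(fit)
fit_diffusion <- function(trace, x_m = trace$x_m, start = NULL,
                          lower = c(A = 1e-12, sigma = 0.01, D = 1e-8),
                          upper = c(A = Inf, sigma = 1.0, D = 1e-3),
                          burn_in = 120, maxiter = 200) {
  stopifnot(inherits(trace, "diffusion_trace"))
  keep <- trace$times >= burn_in
  times <- trace$times[keep]
  signal <- trace$signal[keep]
  if (length(times) < 10L) stop("need at least 10 samples after burn-in")
  if (stats::sd(signal) == 0) stop("signal is constant; nothing to fit")
  if (all(signal == 0)) stop("signal is identically zero")
  if (is.null(start)) {
    start <- initial_guess(diffusion_trace(times, signal, x_m = x_m,
                                           calibrated = trace$calibrated),
                           x_m = x_m)
  }
  stopifnot(inherits(start, "diffusion_params"))
  start_vec <- c(A = start$A, sigma = start$sigma, D = start$D)
  start_vec <- pmin(pmax(start_vec, lower + 1e-15), pmin(upper, 1e6 * start_vec))

  df <- data.frame(t = times, y = signal)
  fit <- try(minpack.lm::nlsLM(
    y ~ 2 * A / sqrt(pi) * exp(-x_m^2 / (2 * sigma^2 + 4 * D * t)) /
      sqrt(2 * sigma^2 + 4 * D * t),
    data = df, start = as.list(start_vec),
    lower = lower[c("A", "sigma", "D")], upper = upper[c("A", "sigma", "D")],
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-12, ptol = 1e-12)),
    silent = TRUE)

  if (inherits(fit, "try-error")) {
    res <- structure(list(params = start, std_errors = rep(NA_real_, 3),
                          fit_error_pct = NA_real_, rmse = NA_real_,
                          r2 = NA_real_, n_used = length(times),
                          converged = FALSE, x_m = x_m,
                          times = times, signal = signal, nls = NULL),
                     class = "fick_fit")
    warning("nonlinear fit failed to converge: ",
            attr(fit, "condition")$message)
    return(res)
  }

  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(est)
  fitted_vals <- stats::fitted(fit)
  resid_vals <- signal - fitted_vals
  rmse <- sqrt(mean(resid_vals^2))
  r2 <- stats::cor(signal, fitted_vals)^2
  converged <- isTRUE(fit$convInfo$isConv) || fit$convInfo$stopCode %in% 1:4

  structure(list(
    params = diffusion_params(A = est[["A"]], sigma = est[["sigma"]],
                              D = est[["D"]]),
    std_errors = se,
    fit_error_pct = 100 * se[["D"]] / est[["D"]],
    rmse = rmse, r2 = r2, n_used = length(times),
    converged = converged, x_m = x_m,
    times = times, signal = signal, nls = fit),
    class = "fick_fit")
}

#' @export
coef.fick_fit <- function(object, ...) {
  c(A = object$params$A, sigma = object$params$sigma, D = object$params$D)
}

#' @export
vcov.fick_fit <- function(object, ...) {
  if (is.null(object$nls)) stop("fit did not converge; no covariance")
  stats::vcov(object$nls)
}

#' @export
fitted.fick_fit <- function(object, ...) {
  fick_concentration(object$params, object$x_m, object$times)
}

#' @export
residuals.fick_fit <- function(object, ...) {
  object$signal - stats::fitted(object)
}

#' Predict the fitted diffusion model
#'
#' @param object A `fick_fit`.
#' @param times New sampling times, s; defaults to the fitted times.
#' @param x Observation height, cm; defaults to the fitted height.
#' @param ... Unused.
#' @return Predicted signal values.
#' @export
predict.fick_fit <- function(object, times = object$times, x = object$x_m,
                             ...) {
  fick_concentration(object$params, x, times)
}

#' @export
print.fick_fit <- function(x, ...) {
  cat("Closed-form diffusion fit (Fick's second law, half-Gaussian source)\n")
  cat(sprintf("  observation height x_m = %.3g cm, n = %d samples\n",
              x$x_m, x$n_used))
  cat(sprintf("  A     = %.4g nmol/cm^2 (SE %.2g)\n", x$params$A,
              x$std_errors[["A"]]))
  cat(sprintf("  sigma = %.4g cm       (SE %.2g)\n", x$params$sigma,
              x$std_errors[["sigma"]]))
  cat(sprintf("  D     = %.4g cm^2/s   (SE %.2g, fit error %.3g%%)\n",
              x$params$D, x$std_errors[["D"]], x$fit_error_pct))
  cat(sprintf("  RMSE = %.3g, R^2 = %.6g, converged: %s\n",
              x$rmse, x$r2, x$converged))
  invisible(x)
}

#' @export
summary.fick_fit <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(Estimate = est, `Std. Error` = object$std_errors,
                    check.names = FALSE)
  structure(list(table = tab, rmse = object$rmse, r2 = object$r2,
                 n_used = object$n_used, converged = object$converged,
                 fit_error_pct = object$fit_error_pct),
            class = "summary.fick_fit")
}

#' @export
print.summary.fick_fit <- function(x, ...) {
  cat("Diffusion model fit\n\nParameters:\n")
  print(x$table)
  cat(sprintf("\nRMSE: %.4g   R^2: %.6g   n: %d   fit error (D): %.3g%%\n",
              x$rmse, x$r2, x$n_used, x$fit_error_pct))
  invisible(x)
}

#' Plot a fitted diffusion trace
#'
#' Observed signal (points) with the fitted closed-form curve (line).
#'
#' @param x A `fick_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fick_fit <- function(x, ...) {
  graphics::plot(x$times / 3600, x$signal, pch = 16, cex = 0.4,
                 xlab = "time (h)", ylab = "signal",
                 main = sprintf("Diffusion fit at x_m = %.3g cm", x$x_m), ...)
  tt <- seq(min(x$times), max(x$times), length.out = 400)
  graphics::lines(tt / 3600, predict(x, times = tt), col = "red", lwd = 2)
  invisible(x)
}

#' Simulate replicate traces from a fitted model
#'
#' Draws `nsim` noisy replicates of the fitted trace using the residual RMSE
#' as additive Gaussian noise.
#'
#' @param object A `fick_fit`.
#' @param nsim Number of replicates.
#' @param seed RNG seed (required).
#' @param ... Unused.
#' @return A list of [diffusion_trace()] objects.
#' @export
simulate.fick_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("a seed is required for simulation")
  noise <- trace_noise(additive_sd = object$rmse, seed = seed)
  lapply(seq_len(nsim), function(i) {
    simulate_trace(object$params, x_m = object$x_m, times = object$times,
                   noise = trace_noise(additive_sd = object$rmse,
                                       seed = seed + i - 1L))
  })
}

#' Fit a per-mucin-concentration series of traces
#'
#' Fits each trace of a concentration series (one trace per mucin
#' concentration, concentration 0 = plain water defining `D_0`) and collects
#' the estimates for downstream relative-diffusivity analysis.
#'
#' @param traces Named list of [diffusion_trace()] objects; names are mucin
#'   concentrations in % w/w and must include `"0"`.
#' @param x_m Observation height, cm.
#' @param ... Passed to [fit_diffusion()].
#'
#' @return A list with `fits` (list of `fick_fit`), `series` (a
#'   [mucin_series()] of the fitted D values) and `table` (a data.frame of
#'   estimates per concentration).
#' @export
fit_diffusivity_series <- function(traces, x_m, ...) {
  if (is.null(names(traces)) || any(names(traces) == "")) {
    stop("traces must be named by mucin concentration (%% w/w)")
  }
  conc <- as.numeric(names(traces))
  if (anyNA(conc)) stop("trace names must be numeric concentrations")
  if (anyDuplicated(conc)) stop("duplicate concentration keys")
  if (!any(conc == 0)) {
    stop("the series must include concentration 0 (plain water, D_0)")
  }
  ord <- order(conc)
  conc <- conc[ord]
  traces <- traces[ord]
  fits <- lapply(traces, fit_diffusion, x_m = x_m, ...)
  D_hat <- vapply(fits, function(f) f$params$D, numeric(1))
  A_hat <- vapply(fits, function(f) f$params$A, numeric(1))
  tab <- data.frame(mucin_pct = conc, D = D_hat, A = A_hat,
                    sigma = vapply(fits, function(f) f$params$sigma,
                                   numeric(1)),
                    fit_error_pct = vapply(fits, function(f) f$fit_error_pct,
                                           numeric(1)),
                    converged = vapply(fits, function(f) f$converged,
                                       logical(1)))
  list(fits = fits,
       series = mucin_series(concentrations = conc, D_values = D_hat),
       table = tab)
}
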