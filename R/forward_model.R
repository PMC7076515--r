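#' Closed-form concentration field of a diffusing half-Gaussian layer
#'
#' Evaluates the short-time solution of Fick's second law on the half-line
#' `x >= 0` with a reflecting wall at the cuvette bottom, for an initial
#' half-Gaussian layer of areal amount `A` and width `sigma`:
#'
#' \deqn{c(x,t) = \frac{2A}{\sqrt{\pi}} \,
#'   \frac{\exp\!\left(-x^2/(2\sigma^2 + 4Dt)\right)}
#'        {\sqrt{2\sigma^2 + 4Dt}}}
#'
#' The solution is valid for times `t << h^2/D` and positions `x << h`,
#' before reflections from the top of the water column matter (see
#' [check_validity()] and [solve_fick()] for the finite-domain reference).
#'
#' @param params A [diffusion_params()] object.
#' @param x Height above the cuvette bottom, cm (vectorised, all >= 0).
#' @param t Time since injection, s (vectorised, all >= 0).
#'
#' @return Concentration in nmol/cm^3 (recycled over `x` and `t`).
#' @export
#'
#' @examples
#' caf <- diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)
#' fick_concentration(caf, x = 0, t = 0)        # peak of the initial layer
#' fick_concentration(caf, x = 0.51, t = 13671) # near the trace maximum
fick_concentration <- function(params, x, t) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be nonnegative")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be nonnegative")
  v <- 2 * params$sigma^2 + 4 * params$D * t
  2 * params$A / sqrt(pi) * exp(-x^2 / v) / sqrt(v)
}

#' Sampled time trace at a fixed observation height
#'
#' @param times Sampling times, s, strictly increasing.
#' @param signal Signal values (concentration nmol/cm^3, or raw absorbance).
#' @param x_m Observation height, cm.
#' @param calibrated Logical; `TRUE` when `signal` is in concentration units.
#'
#' @return An object of class `diffusion_trace`.
#' @export
diffusion_trace <- function(times, signal, x_m, calibrated = FALSE) {
  if (length(times) == 0L) stop("trace must contain at least one sample")
  if (length(times) != length(signal)) {
    stop("times and signal must have the same length")
  }
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be nonnegative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 x_m = x_m, calibrated = isTRUE(calibrated)),
            class = "diffusion_trace")
}

#' @export
print.diffusion_trace <- function(x, ...) {
  cat(sprintf("Diffusion trace: %d samples over %.3g h at x_m = %.3g cm (%s)\n",
              length(x$times), max(x$times) / 3600, x$x_m,
              if (x$calibrated) "concentration units" else "raw signal"))
  invisible(x)
}

#' Evaluate the closed-form model as a time trace
#'
#' @param params A [diffusion_params()] object.
#' @param x_m Observation height, cm.
#' @param times Sampling times, s, strictly increasing.
#'
#' @return A calibrated [diffusion_trace()].
#' @export
#'
#' @examples
#' caf <- diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)
#' tr <- eval_trace(caf, x_m = 0.51, times = seq(120, 64800, by = 120))
eval_trace <- function(params, x_m, times) {
  diffusion_trace(times, fick_concentration(params, x_m, times),
                  x_m = x_m, calibrated = TRUE)
}

#' Total diffusing amount at time t
#'
#' Quadrature of the concentration profile over `[0, Inf)`.  Mass
#' preservation is built into the closed form, so the result equals `A` for
#' every `t`; this operation exists to assert that identity numerically.
#' Integration is truncated at `sigma + 10 * sqrt(sigma^2 + 2 D t)`, beyond
#' which the Gaussian tail is negligible (< 1e-20 of the total).
#'
#' @param params A [diffusion_params()] object.
#' @param t Time, s.
#'
#' @return Areal amount, nmol/cm^2.
#' @export
total_mass <- function(params, t) {
  stopifnot(inherits(params, "diffusion_params"))
  if (!is.finite(t) || t < 0) stop("t must be nonnegative")
  upper <- params$sigma + 10 * sqrt(params$sigma^2 + 2 * params$D * t)
  stats::integrate(function(x) fick_concentration(params, x, t),
                   lower = 0, upper = upper,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

#' Time at which the trace at height x peaks
#'
#' The fixed-position time trace of the closed-form model has a unique
#' interior maximum at `t = (x^2 - sigma^2) / (2 D)` whenever `x > sigma`;
#' for `x <= sigma` the trace decays monotonically (the observation point
#' starts inside the source layer).  Used for initial guesses and trace QC.
#'
#' @param params A [diffusion_params()] object.
#' @param x Observation height, cm; must exceed `sigma`.
#'
#' @return Peak time, s.
#' @export
#'
#' @examples
#' peak_time(diffusion_params(111, 0.11, 9.07e-6), x = 0.51)  # ~3.8 h
peak_time <- function(params, x) {
  stopifnot(inherits(params, "diffusion_params"))
  if (!is.finite(x) || x <= params$sigma) {
    stop("no interior maximum: x must exceed sigma")
  }
  (x^2 - params$sigma^2) / (2 * params$D)
}

#' Check the short-time / near-wall validity regime of the closed form
#'
#' The closed form ignores the far wall of the water column, so it requires
#' `t << h^2/D` and `x << h`.  Both conditions are quantified as
#' dimensionless ratios and compared against configurable thresholds.
#'
#' @param params A [diffusion_params()] object.
#' @param geometry A [cuvette_geometry()] object.
#' @param t_max Largest time of interest, s.
#' @param t_threshold Maximum allowed `t_max * D / h^2` (default 0.1).
#' @param x_threshold Maximum allowed `h_m / h` (default 0.25).
#'
#' @return An object of class `validity_report` with fields `t_ratio`,
#'   `x_ratio` and `valid`.
#' @export
#'
#' @examples
#' caf <- diffusion_params(111, 0.11, 9.07e-6)
#' check_validity(caf, default_geometry(), t_max = 18 * 3600)
check_validity <- function(params, geometry, t_max,
                           t_threshold = 0.1, x_threshold = 0.25) {
  stopifnot(inherits(params, "diffusion_params"),
            inherits(geometry, "cuvette_geometry"))
  t_ratio <- t_max * params$D / geometry$h^2
  x_ratio <- geometry$h_m / geometry$h
  structure(list(t_ratio = t_ratio, x_ratio = x_ratio,
                 t_threshold = t_threshold, x_threshold = x_threshold,
                 valid = t_ratio <= t_threshold && x_ratio <= x_threshold),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "Short-time regime: t*D/h^2 = %.3g (<= %.3g), x_m/h = %.3g (<= %.3g) -> %s\n",
    x$t_ratio, x$t_threshold, x$x_ratio, x$x_threshold,
    if (x$valid) "valid" else "OUTSIDE validity regime"))
  invisible(x)
}
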