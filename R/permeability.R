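#' Acceptor-replacement permeation experiment
#'
#' Sampling schedule of a Transwell-type permeation assay (e.g. the
#' mucus-PVPA) in which the insert is moved to fresh acceptor medium at each
#' sampling time, so every measured acceptor concentration reflects only the
#' drug transported during that interval.
#'
#' @param sample_times Sampling times, h, strictly increasing.
#' @param acceptor_concentrations Drug concentration found in the acceptor
#'   at each sampling, nmol/mL.
#' @param V_acceptor Acceptor volume, mL (default 0.6).
#' @param S Barrier surface area, cm^2 (default 0.33).
#' @param C_d Donor concentration, nmol/mL.
#' @param V_donor Donor volume, uL (default 100).
#'
#' @return An object of class `permeation_experiment`.
#' @export
#'
#' @examples
#' permeation_experiment(c(1, 2, 3, 3.5, 4, 4.5, 5, 5.5),
#'                       rep(10, 8), C_d = 1000)
permeation_experiment <- function(sample_times, acceptor_concentrations,
                                  V_acceptor = 0.6, S = 0.33, C_d,
                                  V_donor = 100) {
  if (length(sample_times) != length(acceptor_concentrations)) {
    stop("sample_times and acceptor_concentrations lengths differ")
  }
  if (any(diff(sample_times) <= 0)) stop("sample times must be increasing")
  if (any(!is.finite(acceptor_concentrations)) ||
      any(acceptor_concentrations < 0)) {
    stop("acceptor concentrations must be nonnegative")
  }
  if (any(c(V_acceptor, S, C_d, V_donor) <= 0)) {
    stop("V_acceptor, S, C_d and V_donor must be positive")
  }
  structure(list(sample_times = as.numeric(sample_times),
                 acceptor_concentrations = as.numeric(acceptor_concentrations),
                 V_acceptor = V_acceptor, S = S, C_d = C_d,
                 V_donor = V_donor),
            class = "permeation_experiment")
}

#' Default mucus-PVPA sampling schedule
#'
#' Fresh acceptor compartments after 1, 2, 3, 3.5, 4, 4.5 and 5 h, with a
#' final quantification at 5.5 h.
#'
#' @return Sampling times in hours.
#' @export
default_sampling_times <- function() c(1, 2, 3, 3.5, 4, 4.5, 5, 5.5)

#' Cumulative permeated amount
#'
#' Because the acceptor medium is replaced at each sampling, interval
#' amounts are independent and the cumulative amount is their running sum:
#' `Q(t_k) = sum_{i<=k} C_i * V_acceptor`.
#'
#' @param exp A [permeation_experiment()].
#'
#' @return Numeric vector `Q` in nmol, one value per sampling time
#'   (nondecreasing).
#' @export
cumulative_amount <- function(exp) {
  stopifnot(inherits(exp, "permeation_experiment"))
  cumsum(exp$acceptor_concentrations * exp$V_acceptor)
}

#' Steady-state slope of the cumulative permeation curve
#'
#' OLS slope of `Q` against time over the steady-state window.  The default
#' window takes all samplings from 3 h onward, where the dense second half
#' of the schedule sits; a window linearity below `r2_warn` triggers a
#' warning, and a decreasing `Q` is flagged as nonphysical.
#'
#' @param Q Cumulative amounts, nmol.
#' @param times Sampling times, s.
#' @param window_start Window start, s (default 3 h).
#' @param r2_warn Warn when the window R^2 falls below this (default 0.99).
#'
#' @return A list with `dQdt` (nmol/s), `r2_window`, `window` (indices used)
#'   and `nonphysical` (TRUE when Q decreases anywhere).
#' @export
steady_state_slope <- function(Q, times, window_start = 3 * 3600,
                               r2_warn = 0.99) {
  if (length(Q) != length(times)) stop("Q and times lengths differ")
  nonphysical <- any(diff(Q) < 0)
  if (nonphysical) warning("cumulative amount decreases: nonphysical data")
  window <- which(times >= window_start)
  if (length(window) < 3L) stop("steady-state window has fewer than 3 points")
  fit <- stats::lm(Q[window] ~ times[window])
  r2 <- if (stats::sd(Q[window]) == 0) 1 else
    stats::cor(Q[window], times[window])^2
  if (is.finite(r2) && r2 < r2_warn) {
    warning(sprintf("steady-state window R^2 = %.3f below %.2f", r2, r2_warn))
  }
  list(dQdt = unname(stats::coef(fit)[2]), r2_window = r2,
       window = window, nonphysical = nonphysical)
}

#' Apparent permeability
#'
#' `P_app = (dQ/dt) / (S * C_d)`.  With dQ/dt in nmol/s, S in cm^2 and C_d
#' in nmol/mL (= nmol/cm^3), the result is in cm/s directly.
#'
#' @param dQdt Steady-state slope, nmol/s.
#' @param S Barrier surface area, cm^2.
#' @param C_d Donor concentration, nmol/mL.
#'
#' @return Apparent permeability, cm/s.
#' @export
#'
#' @examples
#' apparent_permeability(0.003, S = 0.33, C_d = 1000)  # 9.09e-6 cm/s
apparent_permeability <- function(dQdt, S, C_d) {
  if (!is.finite(S) || S <= 0) stop("S must be positive")
  if (!is.finite(C_d) || C_d <= 0) stop("C_d must be positive")
  if (!is.finite(dQdt) || dQdt < 0) stop("dQdt must be nonnegative")
  dQdt / (S * C_d)
}

#' Check that sink conditions were maintained
#'
#' Sink conditions require the total transported amount to stay a small
#' fraction of the donor load, so back-flux stays negligible.
#'
#' @param Q_final Final cumulative amount, nmol.
#' @param donor_amount Donor load, nmol.
#' @param threshold Maximum allowed transported fraction (default 0.1).
#'
#' @return `TRUE` when sink conditions held.
#' @export
sink_check <- function(Q_final, donor_amount, threshold = 0.1) {
  if (!is.finite(donor_amount) || donor_amount <= 0) {
    stop("donor amount must be positive")
  }
  Q_final / donor_amount <= threshold
}

#' Full apparent-permeability analysis of a permeation experiment
#'
#' Convenience wrapper: cumulative amount, steady-state slope, P_app and
#' sink check in one call.
#'
#' @param exp A [permeation_experiment()].
#' @param window_start Steady-state window start, s.
#' @param sink_threshold Sink-condition threshold.
#'
#' @return An object of class `papp_result` with fields `dQdt`, `Papp`,
#'   `window`, `r2_window`, `sink_ok` and `Q`.
#' @export
papp_analysis <- function(exp, window_start = 3 * 3600,
                          sink_threshold = 0.1) {
  stopifnot(inherits(exp, "permeation_experiment"))
  Q <- cumulative_amount(exp)
  times_s <- exp$sample_times * 3600
  ss <- steady_state_slope(Q, times_s, window_start = window_start)
  papp <- apparent_permeability(ss$dQdt, exp$S, exp$C_d)
  donor_amount <- exp$C_d * exp$V_donor / 1000   # uL -> mL
  structure(list(dQdt = ss$dQdt, Papp = papp, window = ss$window,
                 r2_window = ss$r2_window,
                 sink_ok = sink_check(Q[length(Q)], donor_amount,
                                      sink_threshold),
                 Q = Q, times_s = times_s),
            class = "papp_result")
}

#' @export
print.papp_result <- function(x, ...) {
  cat(sprintf("Apparent permeability: P_app = %.4g cm/s\n", x$Papp))
  cat(sprintf("  dQ/dt = %.4g nmol/s over %d window points (R^2 = %.4f)\n",
              x$dQdt, length(x$window), x$r2_window))
  cat(sprintf("  sink conditions: %s\n",
              if (x$sink_ok) "maintained" else "VIOLATED"))
  invisible(x)
}

#' Correlation between apparent permeability and diffusivity
#'
#' OLS (with intercept) of `P_app` on `D` across drugs, with an optional
#' exclusion list for compounds whose diffusivity readout is unreliable at
#' a given condition.
#'
#' @param Papp Apparent permeabilities, cm/s.
#' @param D Diffusion coefficients, cm^2/s.
#' @param labels Optional compound labels (needed when `exclude` is used).
#' @param exclude Labels to drop before the regression.
#'
#' @return A `regression_result`.
#' @export
papp_diffusivity_correlation <- function(Papp, D, labels = NULL,
                                         exclude = character(0)) {
  if (length(Papp) != length(D)) stop("Papp and D lengths differ")
  keep <- rep(TRUE, length(Papp))
  if (length(exclude)) {
    if (is.null(labels)) stop("labels required when excluding compounds")
    keep <- !(labels %in% exclude)
  }
  if (sum(keep) < 3L) stop("fewer than 3 pairs after exclusion")
  ols_result(x = D[keep], y = Papp[keep])
}
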