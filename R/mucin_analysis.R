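#' Per-concentration diffusivity series
#'
#' Holds the diffusion coefficients of one drug measured at several mucin
#' concentrations; concentration 0 (plain water) defines the baseline `D_0`
#' for relative-diffusivity statistics.
#'
#' @param concentrations Mucin concentrations, % w/w, nonnegative and unique.
#' @param D_values Diffusion coefficients, cm^2/s, one per concentration.
#' @param drug_label Optional compound label.
#'
#' @return An object of class `mucin_series`, sorted by concentration.
#' @export
mucin_series <- function(concentrations, D_values, drug_label = "") {
  if (length(concentrations) != length(D_values)) {
    stop("concentrations and D_values must have the same length")
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("concentrations must be nonnegative")
  }
  if (anyDuplicated(concentrations)) stop("concentrations must be unique")
  if (any(!is.finite(D_values)) || any(D_values <= 0)) {
    stop("all D values must be positive")
  }
  ord <- order(concentrations)
  structure(list(concentrations = concentrations[ord],
                 D_values = D_values[ord], drug_label = drug_label),
            class = "mucin_series")
}

#' @export
print.mucin_series <- function(x, ...) {
  cat(sprintf("Mucin diffusivity series%s:\n",
              if (nzchar(x$drug_label)) paste0(" (", x$drug_label, ")") else ""))
  print(data.frame(mucin_pct = x$concentrations, D = x$D_values))
  invisible(x)
}

#' Percentage reduction of diffusivity relative to plain water
#'
#' `100 * (1 - D_rel / D_0)`.  A `D_rel` exceeding `D_0` yields a negative
#' reduction and a warning (physically suspicious but not an error).
#'
#' @param D_0 Baseline diffusivity in water, cm^2/s.
#' @param D_rel Diffusivity in the presence of mucin, cm^2/s.
#'
#' @return Percentage reduction.
#' @export
#'
#' @examples
#' percent_reduction(9.07e-6, 6.08e-6)  # ~33% for caffeine at 0.1% mucin
percent_reduction <- function(D_0, D_rel) {
  if (!is.finite(D_0) || D_0 <= 0) stop("D_0 must be positive")
  if (any(!is.finite(D_rel)) || any(D_rel < 0)) {
    stop("D_rel must be nonnegative")
  }
  if (any(D_rel > D_0)) {
    warning("D_rel exceeds D_0: negative reduction reported")
  }
  100 * (1 - D_rel / D_0)
}

#' Per-concentration reduction table
#'
#' @param series A [mucin_series()] including concentration 0.
#'
#' @return A data.frame with columns `mucin_pct`, `D` and `reduction_pct`
#'   (exactly 0 at concentration 0).
#' @export
reduction_table <- function(series) {
  stopifnot(inherits(series, "mucin_series"))
  i0 <- which(series$concentrations == 0)
  if (length(i0) != 1L) {
    stop("series must contain the baseline concentration 0")
  }
  D_0 <- series$D_values[i0]
  red <- percent_reduction(D_0, series$D_values)
  red[i0] <- 0
  data.frame(mucin_pct = series$concentrations, D = series$D_values,
             reduction_pct = red)
}

#' Apply a reduction table to a baseline diffusivity
#'
#' Inverse of [reduction_table()]: rebuilds the per-concentration D values
#' from a baseline `D_0` and percentage reductions.
#'
#' @param D_0 Baseline diffusivity, cm^2/s.
#' @param concentrations Mucin concentrations, % w/w.
#' @param reductions_pct Percentage reductions (0 at concentration 0).
#'
#' @return A [mucin_series()].
#' @export
#'
#' @examples
#' # mucin self-diffusion: 3.1e-6 cm^2/s at 0.1% with a 14% reduction
#' # implies D_0 = 3.6e-6; a 39% reduction then gives 2.2e-6 at 0.6%
#' s <- apply_reductions(3.1e-6 / (1 - 0.14), c(0, 0.1, 0.6), c(0, 14, 39))
apply_reductions <- function(D_0, concentrations, reductions_pct) {
  mucin_series(concentrations, D_0 * (1 - reductions_pct / 100))
}

#' Linearity of inverse diffusivity against mucin concentration
#'
#' Under the Stokes-Einstein picture with viscosity linear in mucin
#' concentration, `1/D_rel` is linear in concentration.  Fits ordinary least
#' squares (with intercept) of `1/D` on concentration and reports the
#' squared Pearson correlation.
#'
#' @param series A [mucin_series()] with at least 3 concentrations.
#'
#' @return A `regression_result`: list with `slope`, `intercept`, `r2`, `n`.
#' @export
inverse_D_regression <- function(series) {
  stopifnot(inherits(series, "mucin_series"))
  if (length(series$concentrations) < 3L) {
    stop("need at least 3 concentrations")
  }
  ols_result(x = series$concentrations, y = 1 / series$D_values)
}

# simple OLS with intercept; r2 as the squared Pearson correlation, which
# coincides with the coefficient of determination for this model
ols_result <- function(x, y) {
  if (length(unique(x)) < 2L) stop("degenerate regression: x has no spread")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope = %.6g, intercept = %.6g, R^2 = %.4f, n = %d\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Mass balance of the diffusion experiment
#'
#' Compares the amount of drug inferred from the fitted model,
#' `n_dif = S * A`, with the nominally injected amount `n_i = V_i * C_n`.
#' In plain water the ratio is close to 1; deficits at higher mucin
#' concentrations indicate drug sequestered by mucin and unavailable for
#' diffusion.
#'
#' @param A_fit Fitted areal amount, nmol/cm^2.
#' @param geometry A [cuvette_geometry()].
#' @param C_n Nominal injected concentration, mM.
#'
#' @return A list with `n_dif` (nmol), `n_i` (nmol) and `ratio`.
#' @export
#'
#' @examples
#' mass_balance(111, default_geometry(), C_n = 0.86)  # caffeine: ratio ~ 1.03
mass_balance <- function(A_fit, geometry, C_n) {
  stopifnot(inherits(geometry, "cuvette_geometry"))
  if (!is.finite(A_fit) || A_fit < 0) stop("A_fit must be nonnegative")
  n_dif <- geometry$S * A_fit
  n_i <- nominal_amount(C_n, geometry$V_i)
  list(n_dif = n_dif, n_i = n_i, ratio = n_dif / n_i)
}

#' Regression of fitted amount on nominal concentration
#'
#' If all injected drug takes part in diffusion, `A` is linear in `C_n` with
#' theoretical slope `V_i / S` (nmol/cm^2 per mM).  Returns the OLS fit
#' together with that theoretical slope for comparison.
#'
#' @param C_n Nominal concentrations, mM (>= 3 distinct values).
#' @param A_fit Fitted areal amounts, nmol/cm^2.
#' @param geometry A [cuvette_geometry()].
#'
#' @return A `regression_result` with an extra field `slope_theoretical`.
#' @export
amount_vs_concentration_regression <- function(C_n, A_fit, geometry) {
  stopifnot(inherits(geometry, "cuvette_geometry"))
  if (length(C_n) != length(A_fit)) stop("C_n and A_fit lengths differ")
  if (length(C_n) < 3L) stop("need at least 3 pairs")
  if (length(unique(C_n)) < 2L) stop("degenerate input: all C_n equal")
  res <- ols_result(x = C_n, y = A_fit)
  res$slope_theoretical <- geometry$V_i / geometry$S
  res
}

#' Stokes-Einstein hydrodynamic radius from a diffusivity
#'
#' `r = k_B T / (6 pi eta D)`, converted to nm.  `D` is supplied in cm^2/s
#' and converted internally to SI.
#'
#' @param D Diffusion coefficient, cm^2/s.
#' @param constants A [physical_constants()] object.
#'
#' @return Hydrodynamic radius, nm.
#' @export
#'
#' @examples
#' stokes_einstein_radius(9.07e-6)  # caffeine: ~0.27 nm
stokes_einstein_radius <- function(D, constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (any(!is.finite(D)) || any(D <= 0)) stop("D must be positive")
  D_si <- D * 1e-4                       # cm^2/s -> m^2/s
  r_m <- constants$k_B * constants$T / (6 * pi * constants$eta * D_si)
  r_m * 1e9
}

#' Stokes-Einstein diffusivity from a hydrodynamic radius
#'
#' Exact inverse of [stokes_einstein_radius()].
#'
#' @param r Hydrodynamic radius, nm.
#' @param constants A [physical_constants()] object.
#'
#' @return Diffusion coefficient, cm^2/s.
#' @export
stokes_einstein_D <- function(r, constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  r_m <- r * 1e-9
  D_si <- constants$k_B * constants$T / (6 * pi * constants$eta * r_m)
  D_si * 1e4
}

#' Regression of diffusivity on inverse radius
#'
#' Under Stokes-Einstein, `D` is proportional to `1/r` across compounds at
#' fixed temperature and viscosity; real panels scatter around that line.
#'
#' @param D Diffusion coefficients, cm^2/s (>= 3 values).
#' @param inv_r Inverse hydrodynamic radii, 1/nm.
#'
#' @return A `regression_result`.
#' @export
diffusivity_radius_regression <- function(D, inv_r) {
  if (length(D) != length(inv_r)) stop("D and inv_r lengths differ")
  if (length(D) < 3L) stop("need at least 3 pairs")
  ols_result(x = inv_r, y = D)
}
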