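#' Cuvette geometry for localized-spectroscopy diffusion experiments
#'
#' The experiment injects a small drug volume at the bottom of a water-filled
#' cuvette and records absorbance at a fixed height while the drug diffuses
#' upward.  All downstream computations use a fixed internal unit system:
#' lengths in cm, volumes in microlitres, areas in cm^2.
#'
#' @param h Water-column length, cm.
#' @param h_m Observation height measured from the cuvette bottom, cm.
#' @param S Cuvette cross-section, cm^2.
#' @param V_i Injection volume, microlitres.
#' @param chamber_volume Cuvette chamber volume, microlitres.
#' @param path_length Optical path length, cm.
#'
#' @return An object of class `cuvette_geometry` (a named list).
#' @export
#'
#' @examples
#' geo <- cuvette_geometry()
#' geo$h_m / geo$h   # observation point sits well below the water surface
cuvette_geometry <- function(h = 3.30, h_m = 0.51, S = 0.2, V_i = 25,
                             chamber_volume = 700, path_length = 1.0) {
  vals <- c(h = h, h_m = h_m, S = S, V_i = V_i,
            chamber_volume = chamber_volume, path_length = path_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be positive and finite")
  }
  if (h_m >= h) stop("observation height h_m must be below the water column h")
  if (V_i >= chamber_volume) {
    stop("injection volume V_i must be smaller than the chamber volume")
  }
  structure(as.list(vals), class = "cuvette_geometry")
}

#' Default cuvette geometry
#'
#' The standard 700 uL quartz cuvette setup: 3.30 cm water column, observation
#' at 0.51 cm from the bottom, 0.2 cm^2 cross-section, 25 uL injection,
#' 10 mm optical path.
#'
#' @return A `cuvette_geometry` object.
#' @export
default_geometry <- function() cuvette_geometry()

#' Physical constants for Stokes-Einstein conversions
#'
#' @param T_K Absolute temperature, K. Default 298.15 K (25 C).
#' @param eta Dynamic viscosity of the diffusional medium, Pa s.
#'   Default 0.89e-3 Pa s (water at 25 C).
#'
#' @return An object of class `physical_constants` with fields `k_B` (J/K),
#'   `T` (K) and `eta` (Pa s).
#' @export
physical_constants <- function(T_K = 298.15, eta = 0.89e-3) {
  if (!is.finite(T_K) || T_K <= 0) stop("temperature must be positive")
  if (!is.finite(eta) || eta <= 0) stop("viscosity must be positive")
  structure(list(k_B = 1.380649e-23, T = T_K, eta = eta),
            class = "physical_constants")
}

#' Parameter triple of the closed-form diffusion model
#'
#' The model describes the concentration field of a half-Gaussian drug layer
#' spreading by free diffusion: `A` is the areal amount of diffusing
#' substance (the integral of the concentration profile over height), `sigma`
#' the width of the initial half-Gaussian layer, and `D` the diffusion
#' coefficient.
#'
#' @param A Areal amount, nmol/cm^2 (signal * cm when the trace is
#'   uncalibrated absorbance).
#' @param sigma Initial half-Gaussian width, cm.
#' @param D Diffusion coefficient, cm^2/s.
#'
#' @return An object of class `diffusion_params`.
#' @export
#'
#' @examples
#' diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)  # caffeine in water
diffusion_params <- function(A, sigma, D) {
  vals <- c(A = A, sigma = sigma, D = D)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("A, sigma and D must all be positive and finite")
  }
  structure(list(A = A, sigma = sigma, D = D), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("Diffusion parameters: A = %.4g nmol/cm^2, sigma = %.4g cm, D = %.4g cm^2/s\n",
              x$A, x$sigma, x$D))
  invisible(x)
}

#' Nominal injected amount
#'
#' Amount of drug injected into the cuvette, `n_i = C_n * V_i`.  In the
#' internal unit system 1 mM is identically 1 nmol/uL, so the product of a
#' millimolar concentration and a microlitre volume is an amount in nmol.
#'
#' @param C_n Nominal concentration of the injected solution, mM.
#' @param V_i Injection volume, uL.
#'
#' @return Injected amount, nmol.
#' @export
#'
#' @examples
#' nominal_amount(0.86, 25)   # 21.5 nmol of caffeine
nominal_amount <- function(C_n, V_i) {
  if (!is.finite(C_n) || C_n <= 0) stop("C_n must be positive")
  if (!is.finite(V_i) || V_i <= 0) stop("V_i must be positive")
  C_n * V_i
}

#' Read geometry, constants and fit options from a configuration file
#'
#' The configuration is a flat key-value YAML document.  Recognised keys:
#' `h_cm`, `hm_cm`, `S_cm2`, `Vi_uL`, `chamber_uL`, `path_cm`, `T_K`,
#' `eta_Pa_s`.  Missing keys fall back to the defaults of
#' [cuvette_geometry()] and [physical_constants()].
#'
#' @param path Path to the configuration file.
#'
#' @return A list with components `geometry` and `constants`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a flat key-value document")
  pick <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  geo <- cuvette_geometry(
    h = pick("h_cm", 3.30), h_m = pick("hm_cm", 0.51),
    S = pick("S_cm2", 0.2), V_i = pick("Vi_uL", 25),
    chamber_volume = pick("chamber_uL", 700),
    path_length = pick("path_cm", 1.0))
  cons <- physical_constants(T_K = pick("T_K", 298.15),
                             eta = pick("eta_Pa_s", 0.89e-3))
  list(geometry = geo, constants = cons)
}

#' Reference analytical parameters for the four probe drugs
#'
#' Fitted diffusion parameters in plain water for atenolol (ATN), caffeine
#' (CAF), hydrocortisone (HYD) and naproxen (NPR), as obtained by localized
#' UV-visible spectroscopy: nominal donor concentration `C_n` (mM), water
#' diffusivity `D_0` (cm^2/s), initial areal amount `A_0` (nmol/cm^2) and
#' initial layer width `sigma` (cm).  These serve as realistic ground-truth
#' parameters for synthetic traces and worked examples.
#'
#' @return A data.frame with one row per drug.
#' @export
#'
#' @examples
#' reference_drugs()
reference_drugs <- function() {
  data.frame(
    drug  = c("ATN", "CAF", "HYD", "NPR"),
    C_n   = c(4.99, 0.86, 0.53, 1.01),
    D_0   = c(5.81e-6, 9.07e-6, 6.44e-6, 8.02e-6),
    A_0   = c(648, 111, 69, 133),
    sigma = c(0.11, 0.11, 0.11, 0.13),
    stringsAsFactors = FALSE)
}

#' Reference percentage reductions of diffusivity with mucin concentration
#'
#' Percentage reduction of the diffusion coefficient relative to plain water
#' at porcine gastric mucin concentrations of 0, 0.1, 0.3 and 0.6 % w/w, for
#' the four probe drugs and for mucin itself (MUC, self-diffusion).
#'
#' @return A data.frame with a `mucin_pct` column and one column per compound.
#' @export
reference_reductions <- function() {
  data.frame(
    mucin_pct = c(0, 0.1, 0.3, 0.6),
    ATN = c(0, 24, 47, 63),
    CAF = c(0, 33, 51, 67),
    HYD = c(0, 17, 36, 37),
    NPR = c(0, 25, 53, 65),
    MUC = c(0, 14, 43, 39))
}
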