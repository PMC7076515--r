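#' Instrument noise model for synthetic traces
#'
#' Multiplicative + additive Gaussian noise with optional linear baseline
#' drift, emulating spectrophotometer readout.  A seed is mandatory whenever
#' any noise component is nonzero, so every generated trace is reproducible.
#'
#' @param multiplicative_sd Relative noise SD (fraction of the signal).
#' @param additive_sd Additive noise SD, signal units.
#' @param baseline_drift Linear drift, signal units per hour.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `trace_noise`.
#' @export
trace_noise <- function(multiplicative_sd = 0, additive_sd = 0,
                        baseline_drift = 0, seed = NULL) {
  if (multiplicative_sd < 0 || additive_sd < 0) stop("noise SDs must be >= 0")
  noisy <- multiplicative_sd > 0 || additive_sd > 0
  if (noisy && is.null(seed)) {
    stop("a seed is mandatory for any nonzero noise")
  }
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd,
                 baseline_drift = baseline_drift, seed = seed),
            class = "trace_noise")
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a noisy localized-spectroscopy trace
#'
#' Evaluates the closed-form model at the observation height and applies the
#' noise model:
#' `signal_i = c(x_m, t_i) * (1 + e_mult_i) + e_add_i + drift * t_i / 3600`.
#' Deterministic given the noise seed; with all noise zero the result is
#' identical to [eval_trace()].
#'
#' @param params A [diffusion_params()] object (ground truth).
#' @param x_m Observation height, cm.
#' @param times Sampling times, s.
#' @param noise A [trace_noise()] model.
#'
#' @return A [diffusion_trace()] (marked uncalibrated when noisy).
#' @export
#'
#' @examples
#' caf <- diffusion_params(111, 0.11, 9.07e-6)
#' tr <- simulate_trace(caf, 0.51, seq(120, 64800, 120),
#'                      trace_noise(multiplicative_sd = 0.02, seed = 7))
simulate_trace <- function(params, x_m, times,
                           noise = trace_noise()) {
  stopifnot(inherits(params, "diffusion_params"),
            inherits(noise, "trace_noise"))
  clean <- fick_concentration(params, x_m, times)
  noisy <- noise$multiplicative_sd > 0 || noise$additive_sd > 0
  signal <- if (noisy) {
    with_seed(noise$seed, {
      e_mult <- stats::rnorm(length(times), 0, noise$multiplicative_sd)
      e_add <- stats::rnorm(length(times), 0, noise$additive_sd)
      clean * (1 + e_mult) + e_add
    })
  } else {
    clean
  }
  signal <- signal + noise$baseline_drift * times / 3600
  diffusion_trace(times, signal, x_m = x_m, calibrated = !noisy)
}

#' Mucin effect model for synthetic concentration series
#'
#' Phenomenological model of how mucin alters a drug's diffusion trace:
#' viscosity grows linearly with mucin concentration (reducing D), a
#' concentration-dependent fraction of the drug is bound to mucin and
#' removed from the diffusing pool (reducing A), and mucin itself
#' contributes a constant background signal.
#'
#' @param viscosity_slope Fractional reduction of D per % w/w mucin;
#'   `D(c) = D_0 * (1 - viscosity_slope * c)`.
#' @param bound_slope Bound (non-diffusing) drug fraction per % w/w mucin;
#'   `A(c) = A_0 * (1 - bound_slope * c)`, capped below 1.
#' @param background_absorbance Additive background per % w/w mucin,
#'   signal units.
#'
#' @return An object of class `mucin_effect`.
#' @export
mucin_effect <- function(viscosity_slope = 0, bound_slope = 0,
                         background_absorbance = 0) {
  if (viscosity_slope < 0 || bound_slope < 0 || background_absorbance < 0) {
    stop("effect magnitudes must be nonnegative")
  }
  structure(list(viscosity_slope = viscosity_slope,
                 bound_slope = bound_slope,
                 background_absorbance = background_absorbance),
            class = "mucin_effect")
}

#' Simulate a per-mucin-concentration trace series with known ground truth
#'
#' @param D_0 Baseline diffusivity in water, cm^2/s.
#' @param A_0 Baseline areal amount, nmol/cm^2.
#' @param sigma Initial layer width, cm.
#' @param x_m Observation height, cm.
#' @param times Sampling times, s.
#' @param concentrations Mucin concentrations, % w/w, must include 0.
#' @param effect A [mucin_effect()] model.
#' @param noise A [trace_noise()] model; per-concentration seeds are derived
#'   from `noise$seed` by offsetting.
#'
#' @return A list with `traces` (named list of [diffusion_trace()]) and
#'   `truth` (data.frame of the ground-truth `D`, `A` and bound fraction per
#'   concentration).
#' @export
simulate_mucin_series <- function(D_0, A_0, sigma, x_m, times,
                                  concentrations,
                                  effect = mucin_effect(),
                                  noise = trace_noise()) {
  stopifnot(inherits(effect, "mucin_effect"))
  if (!any(concentrations == 0)) {
    stop("concentrations must include 0 (plain water baseline)")
  }
  D_c <- D_0 * (1 - effect$viscosity_slope * concentrations)
  if (any(D_c <= 0)) {
    stop("viscosity slope drives D to zero or below at the top concentration")
  }
  bound <- pmin(effect$bound_slope * concentrations, 0.999)
  A_c <- A_0 * (1 - bound)
  traces <- vector("list", length(concentrations))
  names(traces) <- as.character(concentrations)
  for (i in seq_along(concentrations)) {
    noise_i <- noise
    if (!is.null(noise$seed)) noise_i$seed <- noise$seed + i - 1L
    tr <- simulate_trace(diffusion_params(A_c[i], sigma, D_c[i]),
                         x_m = x_m, times = times, noise = noise_i)
    if (effect$background_absorbance > 0) {
      tr$signal <- tr$signal +
        effect$background_absorbance * concentrations[i]
    }
    traces[[i]] <- tr
  }
  list(traces = traces,
       truth = data.frame(mucin_pct = concentrations, D = D_c, A = A_c,
                          bound_fraction = bound))
}

#' Simulate an acceptor-replacement permeation experiment
#'
#' Inverse of the apparent-permeability calculation under sink conditions:
#' each interval transports `dQ = Papp * S * C_d * dt`, appearing in the
#' fresh acceptor as concentration `dQ / V_acceptor`.  Generation refuses
#' parameter combinations that break the sink assumption.
#'
#' @param Papp Ground-truth apparent permeability, cm/s.
#' @param template A [permeation_experiment()] providing schedule, geometry
#'   and donor concentration (its `acceptor_concentrations` are ignored).
#' @param noise_sd Relative Gaussian noise SD on each concentration.
#' @param seed RNG seed, mandatory when `noise_sd > 0`.
#' @param max_sink_fraction Largest tolerated transported fraction of the
#'   donor load (default 0.1).
#'
#' @return A [permeation_experiment()] with simulated acceptor
#'   concentrations.
#' @export
simulate_permeation <- function(Papp, template, noise_sd = 0, seed = NULL,
                                max_sink_fraction = 0.1) {
  stopifnot(inherits(template, "permeation_experiment"))
  if (Papp < 0) stop("Papp must be nonnegative")
  if (noise_sd > 0 && is.null(seed)) stop("a seed is mandatory for noise")
  times_s <- template$sample_times * 3600
  dt <- diff(c(0, times_s))
  dQ <- Papp * template$S * template$C_d * dt
  donor_amount <- template$C_d * template$V_donor / 1000
  if (sum(dQ) > max_sink_fraction * donor_amount) {
    stop(sprintf(
      paste("sink assumption violated: %.3g nmol transported vs %.3g nmol",
            "donor load; lower Papp or C_d, or raise the donor volume"),
      sum(dQ), donor_amount))
  }
  conc <- dQ / template$V_acceptor
  if (noise_sd > 0) {
    conc <- with_seed(seed, {
      pmax(conc * (1 + stats::rnorm(length(conc), 0, noise_sd)), 0)
    })
  }
  permeation_experiment(template$sample_times, conc,
                        V_acceptor = template$V_acceptor, S = template$S,
                        C_d = template$C_d, V_donor = template$V_donor)
}
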