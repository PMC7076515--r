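---
title: "Quantifying drug diffusivity in the presence of mucin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug diffusivity in the presence of mucin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucodiff)
```

## The measurement and its model

Localized UV-visible spectroscopy watches a drug layer diffuse up a
water-filled cuvette.  At `t = 0` a small volume (25 µL) of concentrated
drug solution is injected at the bottom of the cuvette under 675 µL of
water, and the absorbance is recorded at a fixed height `x_m = 0.51` cm
from the bottom, every 120 s for 18 h.  As the drug front diffuses past the
beam, the recorded trace rises, peaks, and slowly decays.

`mucodiff` models this with the closed-form solution of Fick's second law
on the half-line `x >= 0` (reflecting wall at the cuvette bottom) for an
initial half-Gaussian layer:

$$c(x,t) = \frac{2A}{\sqrt{\pi}}\,
  \frac{\exp\!\big(-x^2/(2\sigma^2+4Dt)\big)}{\sqrt{2\sigma^2+4Dt}},$$

with three parameters:

* `A` — areal amount of diffusing drug (nmol/cm²); the integral of the
  profile over height, conserved for all `t`;
* `sigma` — width of the initial half-Gaussian layer (cm), set by the
  injection;
* `D` — the diffusion coefficient (cm²/s), the quantity of interest.

The closed form ignores the far wall of the water column, so it is valid
only while `t << h²/D` and `x << h`, with `h = 3.30` cm the water-column
length.  `check_validity()` quantifies both conditions as dimensionless
ratios; the default thresholds (`t·D/h² <= 0.1`, `x_m/h <= 0.25`) were
chosen so that the standard experiment — which sits at about 0.054 and
0.155 — lies comfortably inside, while configurations with meaningful
boundary reflection are flagged.

All quantities use a fixed internal unit system: lengths in cm, time in s,
volumes in µL, concentrations in mM (≡ nmol/µL), areal amounts in nmol/cm².
In this system the standard experiment's numbers come out at order 1–1000,
and apparent permeability lands directly in cm/s.

## Validating the closed form against a finite-domain solver

Because the closed form is an approximation, the package carries an
independent check: `solve_fick()` integrates Fick's second law on the
finite domain `[0, h]` with no-flux boundaries at both ends, using an
explicit FTCS scheme with mirror ghost nodes.  The time step defaults to
`0.4·dx²/D`, inside the stability bound `D·dt/dx² <= 0.5`, and the scheme
conserves the trapezoid mass of the profile exactly in exact arithmetic.
`compare_to_closed_form()` reports the worst relative deviation between the
two routes at the observation height, excluding points where the
closed-form signal is below 1% of the trace maximum (relative error is
meaningless in the flat pre-arrival tail).

```{r oracle}
caf <- diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)
compare_to_closed_form(caf, default_geometry(),
                       t_out = seq(1200, 64800, by = 2400))
```

Inside the validity regime the two agree to a few tenths of a percent; with
a short water column (`h = 1` cm) the deviation grows to tens of percent as
reflections from the top boundary feed back into the trace.  The default
grid (331 nodes) puts the 0.51 cm observation height exactly on a node and
runs in a fraction of a second.

## Fitting

`fit_diffusion()` estimates `(A, sigma, D)` by bounded nonlinear least
squares (Levenberg–Marquardt, via minpack.lm) on the raw trace.  Choices
that matter:

* **Starting values.** `initial_guess()` inverts the model's peak
  relations: the trace at height `x` peaks at `t = (x² − σ²)/(2D)`, so the
  observed peak time gives a `D` guess (with `σ₀ = 0.1` cm as a default
  width), and the peak height gives an `A` guess.  Traces without an
  interior maximum fall back to configured defaults with a warning.
* **Bounds.** `D ∈ [1e-8, 1e-3]` cm²/s brackets all small-molecule aqueous
  diffusivities with a wide margin; `σ ∈ [0.01, 1]` cm brackets plausible
  injection layers in this cuvette.
* **Burn-in.** Samples before 120 s (the first sampling interval) are
  discarded by default, as the injection transient has no model.
* **Loss.** Plain unweighted least squares; the instrument noise has no
  published weighting model.
* **Tolerances.** Relative function/parameter tolerance 1e-12, at most 200
  iterations; non-convergence is returned as a flagged result, never as a
  silent success.
* **Fit error.** Reported as the relative standard error of `D` from the
  Jacobian-based linearised covariance, in percent.  This is the package's
  operational definition of the method's "fitting error"; on noiseless,
  well-conditioned traces it is far below 1%.

Two structural properties are worth knowing.  The model is linear in `A`,
so rescaling the signal (for example, fitting raw absorbance rather than
calibrated concentration) rescales `A` and leaves `sigma` and `D`
untouched — calibration is therefore optional when only diffusivity is
wanted.  And the peak-time relation makes `D` strongly identified by the
peak position, which is why recovery from noiseless traces is exact to
numerical precision even from starting values perturbed by ±50%.

## Mucin-interaction statistics

Dissolving the drug in a mucin dispersion (0.1–0.6% w/w porcine gastric
mucin) and repeating the experiment yields a relative diffusivity
`D_rel` per concentration.  `mucin_series()` and its helpers compute the
derived statistics:

* `reduction_table()` — percentage reduction `100·(1 − D_rel/D_0)` per
  concentration;
* `inverse_D_regression()` — if viscosity grows linearly with mucin
  concentration, Stokes–Einstein makes `1/D_rel` linear in concentration;
  the R² of that line (squared Pearson correlation, which for simple OLS
  with intercept equals the coefficient of determination) measures how much
  of the slowdown pure viscosity explains;
* `mass_balance()` — compares the fitted amount `n_dif = S·A` with the
  injected amount `n_i = V_i·C_n`; a deficit indicates drug bound to mucin
  and withdrawn from the diffusing pool;
* `amount_vs_concentration_regression()` — across drugs, `A` should be
  linear in `C_n` with theoretical slope `V_i/S` (125 nmol/cm² per mM for
  the standard geometry);
* `stokes_einstein_radius()` / `stokes_einstein_D()` — exact
  forward/inverse Stokes–Einstein conversions, defaulting to water at
  25 °C (`T = 298.15` K, `η = 0.89` mPa·s, the midpoint of the 23–25 °C
  room-temperature range of the measurement).

A caution on R² round-trips: the package's reference tables store the
reduction percentages rounded to integers, so R² values recomputed from
them can differ in the third decimal from values computed on unrounded
fitted diffusivities.  The atenolol (0.999) and naproxen (0.987)
inverse-diffusivity correlations survive this rounding; the caffeine and
hydrocortisone ones do not, and the test suite asserts only the former.

## Apparent permeability

In the mucus-PVPA permeation assay the insert is moved to fresh acceptor
medium at each sampling (1, 2, 3, 3.5, 4, 4.5, 5 h, final quantification at
5.5 h), so each measured acceptor concentration reflects only that
interval's transport and the cumulative amount is a running sum.
`papp_analysis()` computes `P_app = (dQ/dt)/(S·C_d)` from the OLS slope of
the cumulative curve over the steady-state window.  The window defaults to
all samplings from 3 h onward — the dense second half of the schedule,
where lag effects have died out — and a window linearity below R² = 0.99
triggers a warning rather than an error.  `sink_check()` verifies that the
total transported amount stayed below 10% of the donor load (configurable),
the condition under which back-flux is negligible and the cumulative curve
is linear.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with known
ground truth:

* `simulate_trace()` — closed-form trace plus multiplicative Gaussian
  noise, additive Gaussian noise, and optional linear baseline drift.  The
  defaults used in the recovery studies are 2% multiplicative noise and no
  additive/drift component, a noise envelope consistent with the method's
  reported experimental reproducibility (experimental error below 5%);
  the instrument's true noise spectrum is not published.
* `simulate_mucin_series()` — viscosity is taken linear in mucin
  concentration (`D(c) = D_0(1 − k·c)`), and a linear-in-concentration
  fraction of drug is bound irreversibly at `t = 0` (reducing `A` only).
  Binding kinetics, mucin network microstructure, pore-size filtering and
  pH effects are deliberately not modelled.
* `simulate_permeation()` — constant-flux transport under sink conditions
  with acceptor replacement; generation refuses parameters whose cumulative
  transport would break the sink assumption.

All generators are pure functions of (parameters, seed); they restore the
global RNG state, and any nonzero noise without a seed is an error.
Passing recovery tests on these generators shows that the estimator inverts
its own forward model under realistic noise; it does not show robustness to
effects the generators omit — injection transients, convection, beam
geometry (the observation is treated as a point at `x_m`, not a 10 mm
beam), mucin's own UV absorbance (a constant background can be generated
but no correction procedure is applied), or non-Gaussian instrument error.

## Problem sizes and numerical choices

The recovery studies use the full experimental grid (540 samples over
18 h); series fits in the test suite thin the grid to every 480 s, which
changes none of the estimates on noiseless data.  Quadrature for the mass
check truncates at `σ + 10·sqrt(σ² + 2Dt)`, beyond which the Gaussian tail
is below 1e-20 of the total.  The finite-difference validation uses 331
nodes and 50-seed noise studies use seeds 1..50; both complete in seconds.
The noise-robustness criterion asserts the median (not maximum) recovery
error, matching how experimental reproducibility is usually quoted.

## Known limitations

* The method requires a chromophore and assumes Beer–Lambert linearity of
  absorbance in concentration.
* `D` estimates lose meaning outside the validity regime; the package
  flags but does not correct boundary-reflection bias (use the
  finite-domain solver directly if a short column must be analysed).
* The bound-fraction picture is equilibrium sequestration; slow binding
  would bias both `A` and `D` in ways the generators do not emulate.
* Absolute permeability values depend on the real barrier; only the
  synthetic round-trip (simulate → analyse) is asserted, not agreement
  with any particular experimental panel.
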