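# mucodiff

Estimates drug diffusion coefficients from localized UV-visible
spectroscopy, and quantifies how mucin — the gel-forming glycoprotein of
mucus — slows drugs down.  It is aimed at pharmaceutics labs that measure
drug–mucus interaction with nothing more than a standard double-beam
spectrophotometer: a concentrated drug layer is injected at the bottom of a
water-filled cuvette, absorbance is recorded at a fixed height
`x_m = 0.51 cm` every 120 s for 18 h, and the rise-peak-decay trace is fit
to the closed-form solution of Fick's second law for a half-Gaussian source
on the half-line:

$$c(x,t) = \frac{2A}{\sqrt{\pi}}\,
  \frac{\exp\!\big(-x^2/(2\sigma^2+4Dt)\big)}{\sqrt{2\sigma^2+4Dt}},
  \qquad \int_0^\infty c(x,t)\,dx = A ,$$

valid for `t ≪ h²/D` and `x ≪ h` (`h` = water-column length, 3.30 cm).
The fit yields the areal amount `A` (nmol/cm²), the initial layer width
`σ` (cm) and the diffusion coefficient `D` (cm²/s).  Around this core the
package provides:

* a finite-difference solver of Fick's second law on the finite cuvette
  with no-flux walls, used to verify the closed form inside its regime and
  quantify its breakdown outside it;
* mucin-interaction statistics: relative diffusivity `D_rel`, percentage
  reductions, linearity of `1/D_rel` in mucin concentration, the
  `n_dif/n_i` mass balance that exposes mucin-bound drug, and
  Stokes–Einstein radius conversions `D = k_BT/(6\pi\eta r)`;
* apparent permeability `P_app = (dQ/dt)/(S\,C_d)` for
  acceptor-replacement permeation assays (mucus-PVPA);
* seeded synthetic-data generators with known ground truth for
  parameter-recovery studies.

## Worked example

Simulate a realistic caffeine-in-water trace (2% multiplicative instrument
noise) and recover its parameters:

```r
library(mucodiff)

caf <- diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)
tr  <- simulate_trace(caf, x_m = 0.51, times = seq(120, 64800, by = 120),
                      noise = trace_noise(multiplicative_sd = 0.02, seed = 1))
fit_diffusion(tr)
#> Closed-form diffusion fit (Fick's second law, half-Gaussian source)
#>   observation height x_m = 0.51 cm, n = 540 samples
#>   A     = 111.1 nmol/cm^2 (SE 0.13)
#>   sigma = 0.1097 cm       (SE 0.0019)
#>   D     = 9.094e-06 cm^2/s   (SE 4.4e-08, fit error 0.483%)
#>   RMSE = 1.75, R^2 = 0.99105, converged: TRUE
```

The true `D` of 9.07e-6 cm²/s is recovered to 0.3% despite the noise, with
a reported fit error below 0.5%.  The mucin analysis starts from one
diffusivity per mucin concentration — here atenolol's water value with its
known reductions — and asks how much of the slowdown viscosity explains:

```r
atn <- apply_reductions(5.81e-6, c(0, 0.1, 0.3, 0.6), c(0, 24, 47, 63))
reduction_table(atn)
#>   mucin_pct          D reduction_pct
#> 1       0.0 5.8100e-06             0
#> 2       0.1 4.4156e-06            24
#> 3       0.3 3.0793e-06            47
#> 4       0.6 2.1497e-06            63
inverse_D_regression(atn)
#> OLS: slope = 485958, intercept = 175640, R^2 = 0.9993, n = 4
```

An R² of 0.999 for `1/D_rel` vs concentration means a viscosity that grows
linearly with mucin concentration accounts for essentially all of
atenolol's slowdown.  Finally, `stokes_einstein_radius(9.094e-6)` returns
0.27 nm — the hydrodynamic radius consistent with a small-molecule
diffusivity in water at 25 °C.

A thin command-line wrapper with `simulate`, `fit-trace`, `mucin-series`,
`permeability` and `validate` subcommands lives at `inst/cli/mucodiff`
(installed under `system.file("cli", "mucodiff", package = "mucodiff")`).

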