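# duospec

Simultaneous quantification of two spectrally overlapped UV absorbers —
a ciprofloxacin-like and an ornidazole-like component — from absorption
spectra, for analytical chemists and chemometricians who need to resolve
a binary mixture without chromatographic separation.

Three independent resolutions of the overlap are implemented end to end:

- **Fourier self-deconvolution (FSD)**: the spectrum's interferogram is
  multiplied by `exp(pi * w * |x|) * D(x)` to cancel an assumed Lorentzian
  broadening of FWHM `w`, narrowing bands until the interferent's
  deconvolved signal crosses zero at a wavelength (λ_zero) where the
  analyte can be calibrated interference-free.
- **Ratio-spectra mean-centering (MC)**: dividing the mixture `A_M = a_X
  C_X + a_Y C_Y` by a pure-Y divisor makes Y's contribution a constant,
  and mean-centering over a wavelength window annihilates constants
  exactly, leaving a signal linear in `C_X`.
- **Neural calibration**: a TANSIG/PURELIN feed-forward net maps the 75
  absorbances of the 279.0–316.0 nm window (0.5 nm) jointly to both
  concentrations, trained from scratch by Levenberg–Marquardt
  (`Δw = (JᵀJ + μI)⁻¹ Jᵀe`, early-stopped on validation) or Bayesian
  regularization (evidence-framework updates of `F = β·E_D + α·E_W`).

Around these sit the standard prediction metrics (MSEP, RRMSEP,
bias-corrected MSEP, recovery), ICH-style validation figures (linearity,
DL/QL, RSD), method-comparison statistics (pooled t, variance-ratio F,
one-way ANOVA), and green-chemistry scoring (modified eco-scale penalty
points `y = a·x^b` and RGB-12 whiteness). A seeded Beer–Lambert
synthetic-spectrum generator with the published 32-mixture training and
10-mixture test concentration designs makes the whole chain reproducible
without instrument data.

## Worked example

```r
library(duospec)

r <- runPipeline("mc", seed = 1)   # simulate, elect divisor/range, calibrate, predict
r$elections$mc_CI
#> $divisor_conc
#> [1] 20
#> $range_nm
#> [1] 260 290
#> $lambda_max_nm
#> [1] 290

round(head(r$predictions, 4), 3)
#>   real_ci real_or pred_ci pred_or  rec_ci  rec_or
#> 1       0    10.0  -0.023   9.950      NA  99.504
#> 2      10    15.0   9.955  15.017  99.554 100.112
#> 3       5    10.5   5.021  10.526 100.430 100.243
#> 4       6    12.0   5.975  11.973  99.584  99.771
```

Each row is one test mixture: the true CI/OR concentrations (µg/ml), the
concentrations predicted from its synthetic spectrum by the
mean-centering calibration, and the percent recovery (undefined where the
true concentration is zero). Here the method recovers a mean 100.05% of
CI and 100.44% of OR at 0.002 AU photometric noise. `runPipeline("fsd",
...)` and `runPipeline("ann", ...)` run the other two methods, logging
their own elections (deconvolution width and λ_zero; architecture and
effective parameters γ).

`reproduceTables()` recomputes every desk-reproducible published figure
(test-table mean recoveries, ANOVA F statistics from the published sums
of squares, quoted critical values, and the worked mean-centering
example) and reports computed vs published with a pass flag.

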