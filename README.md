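# nircal

Near-infrared (NIR) moisture calibration for dried laver (*Porphyra
yezoensis*), for chemometricians and food-quality engineers who need a
tested, reproducible pipeline from spectra to moisture predictions with
honest uncertainty.

Dried laver is graded by moisture content, and the 900–1650 nm NIR window
carries the signal: the O–H first-overtone water band near 1430 nm, the
carbohydrate C–H second overtone near 1180 nm, and polysaccharide–water
interaction bands around 1360–1390 nm. `nircal` implements the complete
calibration workflow:

* **Synthetic spectra generator** — seeded, moisture-coupled Gaussian
  absorption bands with multiplicative/additive scatter and channel
  noise, emulating a 380-sample dried-laver population (moisture
  N(10.18, 2.78²)% truncated to [4.37, 14.84]%) so every stage is
  testable without a download.
* **Preprocessing** — Savitzky–Golay smoothing + first derivative in one
  pass (`sgFirstDerivative`), removing additive baselines exactly.
* **Partitioning** — SPXY max–min selection on the joint normalized
  spectral–chemical distance `d(i,j) = dx/max(dx) + dy/max(dy)`
  (`spxySplit`), with Kennard–Stone (`ksSplit`) as the baseline.
* **Wavelength selection** — a genetic algorithm over binary channel
  masks with cross-validated PLS fitness (negative CV-MSE), elitism, and
  PLS-coefficient importance on standardized predictors (`gaSelect`).
* **Regressors** — XGBoost with the regularized objective
  Ω(f) = γT + ½λ‖w‖², a 1-D CNN (conv 64→128→256, two max pools, two
  dense layers), and a 1-D ResNet-18 (stem + four residual stages, 16
  block convolutions, F(x) + x shortcuts), the networks trained by Adam
  on MSE for an exact epoch count with a native, bit-deterministic
  engine.
* **Uncertainty** — Matern 5/2 Gaussian-process calibration fitted by
  marginal-likelihood maximization; 95% prediction intervals
  μ* ± 1.96 σ* with the noise variance included (`fitGPR`,
  `predictInterval`).
* **Metrics** — R², RMSEP (n−1 divisor), both RPD conventions
  (1/√(1−R²) and SD/RMSEP), PICP (strict bounds), PINAW
  (range-normalized width), CWC = PICP/PINAW, and labeled percent-change
  conventions (`relativeChange`, `selectionEffectReport`).
* **Orchestration** — `runExperiment()` runs the six-cell grid
  (3 models × full/selected wavelengths) from one seeded config and
  persists every stage artifact; `inst/scripts/nircal.R` wraps the
  stages for shell use.

## Worked example

```r
library(nircal)

cfg <- generatorConfig(nSamples = 120, seed = 42)
spectra <- simulateSpectra(cfg)
spectra
#> SpectraSet: 120 samples x 125 channels
#>   wavelengths: 900.0 .. 1650.0 nm
#>   moisture: mean 10.07%, range [4.55, 14.56]

deriv <- sgFirstDerivative(spectra, sgParams(11, 2))
split <- spxySplit(absorbance(deriv), moisture(deriv) / 100, 90)
split
#> SplitResult (spxy): 90 train / 30 test

tr <- trainIndices(split); te <- testIndices(split)
model <- trainXGB(absorbance(deriv)[tr, ], moisture(deriv)[tr] / 100)
pred <- makePredictionSet(model, absorbance(deriv)[te, ],
                          moisture(deriv)[te] / 100, "test", "xgb", "full")
print(pointMetrics(pred), digits = 3)
#>      r2   rmsep rpdEq rpdSdRatio  n
#> 1 0.967 0.00314   5.5        5.5 30
```

Moisture is modeled as a mass fraction, so the RMSEP of 0.00314 means
0.31 percentage points of moisture on held-out samples; R² = 0.967 and
RPD = 5.5 (both conventions coincide here because RPD = SD/RMSEP ≈
1/√(1−R²) when predictions are unbiased) indicate a screening-grade
calibration (RPD > 3).

Interval calibration on the training residuals of a near-interpolating
tree ensemble illustrates a caveat the package surfaces rather than
hides — the GP sees almost no training error, so test intervals
under-cover:

```r
calib <- fitGPR(predictMoisture(model, absorbance(deriv)[tr, ]),
                moisture(deriv)[tr] / 100)
print(intervalMetrics(pred@yActual, predictInterval(calib, pred@yPred)),
      digits = 3)
#>     picp  pinaw  cwc range  n
#> 1 0.0667 0.0147 4.55 0.077 30
```

On a well-specified held-out simulation the same GP machinery achieves
93–97% empirical coverage (see the test suite); the vignette discusses
the calibration protocol.

The package also ships a published six-run reference grid and reproduces
its comparison sentences under explicit percent-change conventions:

```r
print(selectionEffectReport(referenceGrid()), digits = 3)
#>     model metric  full selected       convention percentChange
#> 5     CNN     r2 0.582    0.920  increase_vs_old        58.076
#> 6     CNN    rpd 1.230    2.564  increase_vs_old       108.455
#> 7     CNN  rmsep 0.019    0.008 reduction_vs_new       137.500
#> 8     CNN  pinaw 0.970    0.329  decrease_vs_old        66.082
#> 9  ResNet     r2 0.900    0.464  decrease_vs_old        48.444
#> ...
```

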