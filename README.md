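# lawstress

Left atrial (LA) wall stress after atrial fibrillation (AF) catheter
ablation: measurement, non-invasive prediction, and outcome analysis.

Chronic stretch of the atrial wall is a suspected driver of AF
progression and of arrhythmia recurrence after ablation. Wall stress
summarizes that load through the Law of Laplace for a thin-walled
sphere,

&nbsp;&nbsp;&nbsp;&nbsp;σ = P·r / (2h) = 1333.22 × P × D / (4h)  [dyn/cm²],

with P the peak LA pressure (mmHg), r = D/2 half the echocardiographic
anterior–posterior diameter (mm) and h the mean LA wall thickness (mm).
Each ingredient is hard to obtain — P is invasive, h is sub-millimetre
CT image analysis — which is what this package implements end to end:

* **Wall thickness from CT-like volumes** — multi-Otsu segmentation of
  background / wall / contrast-bright lumen, a harmonic potential
  between endocardium and epicardium (successive over-relaxation on
  the anisotropic 7-point stencil, Dirichlet data at the voxel faces),
  and fixed-step Euler streamline tracing of the normalized gradient:
  `segmentWall()`, `solveLaplace()`, `thicknessMap()`.
* **Stress and quartile stratification** — `lawStress()`,
  `quartilePartition()` (round-half-up boundary ranks: 2223 patients
  split 556/556/555/556), `cohortStress()`.
* **A small 1-D convolutional classifier** predicting top-quartile
  (Q4) stress from eight non-invasive features (non-paroxysmal AF,
  age, hypertension, diabetes, vascular disease, heart failure, LVEF,
  E/Em), trained with Adam, a restarting 20-epoch cosine-annealed
  learning rate from 9.36e-3, stratified batches of 35, dropout 0.2
  and early stopping; five-repeat evaluation with best-model selection
  and a logistic-regression comparator: `buildQ4Net()`,
  `trainQ4Net()`, `repeatAndSelect()`, `fitLogistic()`.
* **Survival analysis of post-blanking recurrence** — Kaplan–Meier
  curves, k-group log-rank tests and Cox proportional-hazards models
  (Efron ties, Wald CIs) with the univariate p < 0.05 screening rule:
  `kmCurve()`, `logrankTest()`, `coxFit()`, `selectThenMultivariate()`,
  plus `linregFit()` for the stress-association models.
* **Synthetic validation data** — shell phantoms with analytically
  known thickness (`shellPhantom()`) and a proportional-hazards cohort
  simulator matched to published covariate summaries
  (`cohortSpec()`, `simulateCohort()`), so every stage is testable
  without patient data.

## Worked example

```r
library(lawstress)

# a noisy spherical-shell phantom with known 2 mm wall, 0.5 mm voxels
ph    <- shellPhantom("concentric", rInner = 10, rOuter = 12,
                      spacing = c(0.5, 0.5, 0.5), noiseSD = 10, seed = 1)
mask  <- segmentWall(ph$volume)
field <- solveLaplace(mask)
th    <- thicknessMap(field)
th
#> ThicknessResult: mean 1.999 mm over 24376 voxels (0.0% flagged)

# wall stress at a typical pressure and diameter
lawStress(P = 20, D = 41, h = meanThickness(th)) / 1e3
#> 136.7        # x 10^3 dyn/cm^2

# a simulated ablation cohort, stratified into stress quartiles
co <- cohortStress(simulateCohort(cohortSpec(n = 2223), seed = 1))
round(attr(co, "cutoffs") / 1e3, 1)
#> 88.8 143.6 195.5

logrankTest(co$follow_up_months, co$recurrence, co$stress_quartile)
#> Log-rank test: chi-square 194.076 on 3 df, p = 8.035e-42
#>  group   n observed expected
#>     Q1 556      180 236.9447
#>     Q2 556      178 234.8952
#>     Q3 555      185 232.2860
#>     Q4 556      329 167.8742
```

The measured mean recovers the true 2 mm wall to 0.1%, the quartile
cutoffs land near the published boundaries (97.4 / 139.8 / 197.9 × 10³
dyn/cm²), and the injected top-quartile hazard excess is exposed by the
log-rank test — the Q4 group accumulates far more recurrences than
expected under equality.

`runPhantomStudy()` and `runCohortStudy()` orchestrate these stages
end to end with per-stage seeds, config hashes and CSV/JSON reports.
The methods vignette (`vignettes/lawstress-methods.Rmd`) documents the
numerical scheme, the generator's assumptions and the package's
limitations.

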