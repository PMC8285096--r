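---
title: "Measuring left atrial wall stress and its prognostic value: methods"
author: "lawstress package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring left atrial wall stress and its prognostic value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Chronic stretch of the left atrial (LA) wall is one of the suspected
drivers of atrial fibrillation (AF) progression and of recurrence after
catheter ablation. Wall *stress* summarizes that load in a single
physiological number, but computing it needs three measurements that are
rarely available together: the peak LA pressure (invasive, measured
during the procedure), the echocardiographic anterior-posterior (AP)
diameter, and the mean LA wall thickness (sub-millimetre, from CT).
`lawstress` implements that measurement chain, the stress computation
and quartile stratification, a small convolutional classifier that
predicts top-quartile stress from eight non-invasive covariates, and
the survival analysis of post-ablation recurrence by stress group —
together with the synthetic phantoms and cohorts needed to validate
every stage, since no patient-level data are publicly deposited.

# Wall thickness by a harmonic potential

## Segmentation

A contrast CT-like volume has three intensity classes: dark
background/myocardium boundary, intermediate wall, and bright
contrast-filled lumen. `segmentWall()`:

1. finds the two multi-Otsu thresholds of the intensity histogram
   (`multiOtsuThresholds()`, an exact dynamic program maximizing
   between-class variance — verified in the tests against exhaustive
   search);
2. takes the lumen as the largest 26-connected bright component;
3. closes the *solid* region (lumen plus wall class) with a 6-neighbour
   structuring element (radius 1 voxel by default) — closing the solid,
   rather than the wall shell, fills noise pinholes of any radial depth
   — then carves the wall out of it and opens it (radius 1) to drop
   speckle;
4. keeps wall components adjacent to the lumen and tags wall voxels as
   endocardial (6-adjacent to lumen) or epicardial (6-adjacent to
   background).

A wall that is not watertight (some lumen voxel touches background
directly) is an error: the potential would short-circuit through the
hole. Both morphology radii are exposed; the defaults assume the wall
is at least about three voxels thick, which holds at the 0.25–0.55 mm
resolutions this measurement is designed for.

## The Laplace potential

On the wall voxels we solve the discrete Laplace equation with
Dirichlet conditions u = 0 on the endocardial interface and u = 1 on
the epicardial interface, using successive over-relaxation (SOR,
omega = 1.8) on the anisotropic 7-point stencil. Convergence is declared
when the largest Gauss–Seidel update of a sweep falls below `tol`
(default 1e-6; the potential has unit range, so this is a relative
measure), with a 10,000-sweep cap and an explicit error, reporting the
residual, on failure. Iterates can overshoot the [0, 1] bounds by
amounts of the order of the tolerance; the returned wall potential is
clamped to [0, 1], so the discrete maximum principle holds exactly for
every converged solve.

One numerical choice matters more than any other here. If the boundary
values are imposed on the *centres* of the outside voxels (the naive
scheme), the effective interface sits half a voxel beyond the anatomy
on each side, and a slab of gap G measures G + h for voxel size h — a
12% error at realistic resolution. We therefore impose the boundary at
the voxel *faces* between wall and non-wall voxels through linear ghost
values, and after convergence extend the field linearly into two layers
of outside voxels so that interpolation and finite differences stay
accurate across the interface. With this scheme the slab phantom is
recovered exactly and the spherical shell to about 0.3%.

Against the closed-form concentric-shell solution
u(r) = (1/R_in − 1/r)/(1/R_in − 1/R_out), the solved potential agrees
to a mean absolute deviation of ~0.3% (and 95th percentile ~1%) away
from the boundaries at 0.25 mm voxels. Isolated voxels deviate by a few
percent near axis-aligned patches of the voxelized boundary: the
staircase surface carries O(h) long-wavelength perturbations that no
mask-based solver can remove, and they shrink with the voxel size. The
package's tests therefore assert the closed-form agreement at the mean
level (1%), not the pointwise maximum.

## Streamline thickness

`thicknessMap()` traces, from every wall voxel centre, the normalized
potential gradient with fixed-step Euler updates (default step 0.2 ×
the smallest voxel spacing, in mm), downhill to the u = 0 level and
uphill to the u = 1 level; the thickness at the voxel is the total arc
length. The crossing of each Dirichlet level is located by linear
back-interpolation of the potential along the final step, which makes
the slab exact independent of the step size. Gradients are central
differences scaled by the physical spacing and sampled trilinearly off
grid. Voxels where the gradient magnitude falls below 1e-8/mm
(disconnected or degenerate wall regions), the step cap is reached, or
the path leaves the grid are flagged and excluded from the mean; a
flagged fraction above 20% raises a warning. The reported mean is the
unweighted average over non-flagged wall voxels (per-voxel lengths, not
unique paths — the alternative sampling set is a documented
interpretation of "mean wall thickness"; averaging per-voxel is the
default because it weights thick and thin regions by wall volume).

On phantoms the signed error of the *mean* thickness is below 0.5% at
all tested resolutions and oscillates around zero, so grid-convergence
is asserted on the mean absolute per-voxel error, which halves per
voxel-size halving (0.128 → 0.077 → 0.038 mm at 1.0/0.5/0.25 mm on the
2 mm shell).

# Wall stress and quartiles

The Law of Laplace for a thin-walled sphere gives the wall stress
sigma = P·r/(2h). With the radius taken as half the echo AP diameter D,

sigma = 1333.22 × P × D / (4 h)  [dyn/cm²],

for P in mmHg and D, h in mm. The conversion constant is stored as
1333.22 internally (and presented rounded as 1333) so that rounding is
not compounded into sigma. No ellipsoidal correction is applied — the
sphericity assumption is inherited from the stress model itself and is
a known limitation.

Cohort stratification uses ascending ranks with boundaries at
round-half-up of k·n/4 (k = 1, 2, 3), ties to the lower group; this is
the convention that reproduces a 556/556/555/556 split of 2223 tie-free
values. Quartiles are computed on all records with a computable stress;
records without a sinus-rhythm pressure are excluded and counted.

# The top-quartile classifier

Eight non-invasive inputs, in fixed order: non-paroxysmal AF, age,
hypertension, diabetes, vascular disease, heart failure, LVEF, E/Em.
(The invasive mean LA voltage is deliberately not an input.) Features
are min-max scaled with coefficients fitted on the training split only;
validation and test values outside [0, 1] are not clipped. A constant
training feature maps to zero with a warning.

The network is deliberately small: eight 3×1 convolution kernels
(stride 1, no padding — and no pooling, so no clinical feature is
discarded), batch normalization, LeakyReLU (slope 0.2), flatten to 48,
then fully connected stacks of 16 and 4 units (each batch norm, ReLU,
dropout 0.2) and one sigmoid output: 945 trainable parameters. Training
uses Adam on the sigmoid cross-entropy loss, initial learning rate
9.36e-3 with a restarting 20-epoch cosine-annealing schedule,
class-stratified mini-batches of 35, early stopping after 10
non-improving validation epochs with best-validation weights restored,
and a 200-epoch cap. Batch-norm evaluation uses running statistics
(momentum 0.9), the standard reading where the reference protocol is
silent. The implementation is explicit R matrix algebra with
hand-derived backpropagation — at this parameter count a deep-learning
framework would add nothing but a dependency — and is exercised by
determinism, parameter-count and separable-data oracles in the tests.

Evaluation reports AUC (rank method), sensitivity and specificity at
the Youden-optimal threshold (the operating rule is not specified by
the protocol; Youden's J is the declared choice), Gini, log-loss
(probabilities clamped at 1e-15) and MSE. Gini is reported as the exact
identity 2·AUC − 1; a printed Gini that disagrees with its printed AUC
by 0.002 is treated as independent rounding. `repeatAndSelect()` runs
five independent split/train/evaluate repeats with derived seeds and
selects the model with the highest validation AUC. The comparator is a
maximum-likelihood logistic fit on the same eight features
(`stats::glm`), with perfect separation flagged and refitted under a
small ridge penalty (`glmnet`).

On simulated cohorts the classifier and the logistic comparator both
reach AUC ≈ 0.63–0.72 against the realized top quartile — the same
moderate-accuracy regime as the clinical report — because only four of
the eight inputs carry signal in the generative model and the noise
share is substantial.

# Survival analysis

Recurrence is analysed from the end of the 3-month blanking period
(times are post-blanking by construction in the simulator; early
recurrences are a separate flag, not the endpoint). Kaplan–Meier
curves, the k-group log-rank test and Cox proportional-hazards fits are
delegated to the `survival` package (Efron tie handling; Wald CIs and
p-values, matching the HR (CI) presentation convention), behind thin
interfaces that add input validation: negative times, single-class
events, zero-variance covariates and monotone likelihood are explicit
errors, and fewer than ten events per covariate warns. The published
model-building rule is implemented literally: every candidate covariate
is screened univariately and those with p < 0.05 enter the joint
multivariate model, with no stepwise refinement. The tests verify the
product-limit curve against a hand oracle, the log-rank statistic
against a hand observed/expected tabulation, a 5% ± 1.5% type-I error
over 1000 null replicates, and ≥93% CI coverage of a true hazard ratio
of 2 over 200 simulations at n = 2000.

# Synthetic data: what it emulates and what it does not

**Phantoms.** Slab, concentric-shell and eccentric-shell geometries
with exact per-voxel thickness (for the eccentric shell, measured along
rays from the inner centre, spanning rOut − rIn ∓ offset). Intensities
are piecewise constant (background 0, wall 100, lumen 300 HU-like) plus
Gaussian noise. This emulates the contrast and resolution regime of
cardiac CT, not its physics: no beam hardening, no partial-volume blur,
no anatomical trabeculation. Default grids are desk-sized (the 2 mm
shell at 0.25 mm voxels is ~1.1M voxels, ~195k wall voxels); full
scanner-sized grids are reachable through the same parameters.

**Cohorts.** Binary covariates are Bernoulli at the published
prevalences (e.g. 28.7% non-paroxysmal AF, 47.1% hypertension);
continuous covariates are log-normal matched to the published
median/IQR summaries (log-normal because the summaries are reported as
median (IQR), signalling right skew). Latent stress follows an additive
linear model on the 10³ dyn/cm² scale whose coefficients are the
published multivariate association estimates (non-paroxysmal AF 31.08,
BMI 2.91, diabetes 15.36, vascular disease 22.27, E/Em 4.95, voltage
−22.24), with intercept 41 and Gaussian noise SD 70 fixed once so that
the realized median and IQR sit near the printed quartile cutoffs
(realized ≈ 86/139/192 vs printed 97.4/139.8/197.9 × 10³ dyn/cm²; the
additive-normal noise makes the simulated distribution more symmetric
than the clinical one — a documented simplification). Peak LA pressure
is *derived* from the latent stress through the Law of Laplace, so the
stress identity holds row-wise and the implied pressure median lands
near 20 mmHg. Recurrence times are exponential proportional hazards
(baseline 0.011/month after blanking, default Q4 hazard ratio 2.43 and
non-paroxysmal AF 1.61), administratively censored uniformly within a
72-month window. Events falling inside the blanking period are either
regenerated post-blanking (default; exact for the memoryless
exponential) or censored at time zero, by configuration. The covariate
correlation structure is not published; the generator is independent by
default and exposes a Gaussian-copula correlation matrix for the
continuous block.

Passing tests on these cohorts therefore demonstrates *protocol and
estimator correctness* (recovery of known effects, calibrated error
rates), not clinical reproduction: the published cohort-specific
numbers (AUC 0.734, HR 2.43, table cells) are not recomputable without
the patient data.

# Problem sizes and runtime

The test-suite and the acceptance script use: phantoms at 0.5 and
0.25 mm voxels (up to ~195k wall voxels; SOR converges in ~100 sweeps
because the wall is thin), cohorts of n = 2223 (the published
development-cohort size), classifier training at n = 1400–1556 training
rows for up to 200 epochs (typically 20–40 before early stopping), 1000
log-rank null replicates and 200 Cox coverage replicates. The entire
acceptance run completes in well under a minute on one CPU.

# Known limitations

* The stress model assumes a thin-walled sphere; regional and
  time-resolved stress are out of scope.
* Thickness is a global mean; no per-segment atlas.
* The staircase boundary of mask-based segmentation leaves O(h)
  pointwise potential deviations (see above); sub-voxel surface
  positioning would require a distance-aware solver and a non-binary
  segmentation.
* The cohort simulator is a proportional-hazards, independence-default
  idealization; it is a validation harness, not a population model.
* Default morphology assumes a wall at least ~3 voxels thick;
  segmentation of a 2-voxel wall (e.g. a 2 mm wall at 1 mm voxels)
  needs the opening radius set to 0.
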