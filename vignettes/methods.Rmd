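---
title: "Pathology-independent posture screening: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathology-independent posture screening: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturescreen)
```

## The screening problem

Clinical classifiers for spinal posture are usually pathology-dependent:
they are trained on healthy subjects *and* on subjects with one specific
pathology, and can detect only that pathology. `posturescreen` implements
the complementary idea of a *pathology-independent* screen: a one-class
support vector machine (OCSVM) learns the density of healthy spinal
posture only, and any measurement falling outside the learned frontier is
flagged as an outlier, whatever its cause. Raw decision values are mapped
to calibrated outlier probabilities with Platt scaling, predictions are
aggregated per subject over repeated measurements, and each prediction is
explained by a local surrogate-model (LIME-style) explainer. A calibrated
random-forest binary classifier provides the conventional
pathology-dependent baseline.

The feature space is the standard rasterstereographic static description
of the spine: 4 pelvic parameters (obliquity, torsion, inclination,
rotation) plus 17 vertebral levels (VP, T1--T12, L1--L4) in 3 anatomical
planes — 55 angles in degrees. Positive values denote rotation/tilt to
the left or ventral (toward flexion).

## The experiment protocol

Both classifier paths share one evaluation protocol, designed so that no
subject's repeated measurements leak across a split:

1. **Grouped 5-fold cross-validation.** Whole subjects are assigned to
   folds, separately per group, so healthy and pathology subjects both
   appear in every fold's test set and each subject is tested exactly
   once.
2. **Validation split.** Within the non-test side of a fold, 20% of
   subjects per group are held out. The healthy validation subjects score
   the OCSVM hyperparameter search; validation subjects of *both* groups
   form the Platt calibration set and score the random-forest search.
3. **Standardization** (per fold) uses the healthy training samples only.
4. **One-class path.** A random search (default 50 draws: kernel uniform
   on {linear, RBF}, `nu` log-uniform on [0.01, 0.5], `gamma` log-uniform
   on [1e-4, 10]) minimizes the fraction of misclassified healthy
   validation *subjects* (a subject is misclassified when more than half
   of its measurements score as outliers); ties prefer smaller `nu`, then
   first-seen order. The winner is trained on healthy training samples
   only and calibrated on the validation scores.
5. **Binary path.** A random forest (search over `n_estimators` 50--500,
   `max_depth` 2--20 or unlimited, selected by validation F1) is trained
   on both groups and calibrated likewise; its raw score is the fraction
   of trees voting "outlier".
6. **Evaluation.** Sample-level confusion matrices at the calibrated 0.5
   probability threshold, F1, Matthews correlation coefficient (MCC) and
   Brier Skill Score (BSS, naive reference = the test set's base rate) per
   fold; across-fold mean and sample SD; subject-level mean probabilities
   with a low-confidence flag when |2·mean − 1| < 0.2.

A single master seed fans out deterministically (`derive_seed()`) to fold
assignment, each fold's searches, model fits and calibration folds, so a
full study reproduces bitwise from one integer.

## The synthetic world

The clinical data this methodology was developed on are not publicly
available, so the package generates a surrogate world with the documented
structure and uses it for all benchmarks.

**Healthy cohort.** Each subject has a stable individual posture around a
physiological population mean (zero in the transversal and coronal
planes, a smooth kyphosis/lordosis-like profile peaking at ±12° in the
sagittal plane, 15° pelvic inclination), and each measurement adds
independent within-subject noise. Between-subject variation is
factor-dominant: 8 latent "postural modes" whose loadings are smooth
Gaussian bumps along the cranio-caudal level ordering (adjacent
vertebrae co-vary, as in real spinal shape data) carry 80% of the
between-subject variance (`factor_variance_share = 0.8`); the remaining
20% is a full-rank idiosyncratic subject offset, because individual
posture never lies exactly in a low-dimensional subspace. Every feature
has between-subject SD 3° and within-subject SD 1° — a 90/10 variance
split consistent with the high test-retest repeatability reported for
rasterstereography.

This split matters for the one-class path, in both directions. The
idiosyncratic component is 55-dimensional white noise at subject level:
it cannot be learned from ~15 training subjects, so occasional new
healthy subjects fall outside any learnable frontier and one-class false
positives concentrate in a few subjects. Setting
`factor_variance_share = 1` (purely low-rank) removes that effect but
concentrates all between-subject spread into the very components the
synthetic classes shift, *widening* subject-level class overlap at a
fixed sample-level silhouette — empirically the harder world for both
classifiers. The default is the committed middle ground; both effects
are reasons why the surrogate world's one-class scores at low separation
sit at the lower end of the reference bands.

Defaults mirror the reference cohort: 25 subjects × 36 measurements,
isolation-forest cleaning that removes the 150/900 most anomalous
samples (dropping subjects left with fewer than 10), then a draw of 10
samples per subject without replacement.

**Synthetic pathology classes.** Standardized PCA is fitted on the
cleaned healthy samples. A class shifts a single principal component:
each synthetic sample reuses a full PC-score row resampled from the
healthy pool (off-mode posture stays healthy-like) and replaces the
target component's standardized score by a draw from Normal(center, 1).
The center is found by monotone bisection — on one frozen stochastic
realization, so the map from center to separation is deterministic —
until the two-cluster silhouette between the class and the healthy
reference (computed in the standardized feature space) hits the target
within ±0.02. The four benchmark classes S1--S4 shift PCs 1--4 toward
silhouettes 0.49, 0.41, 0.33 and 0.16, each with 24 subjects × 10
samples (240 samples, matching the benchmark's per-class totals).

What a green synthetic benchmark does *not* establish: the surrogate
covariance is not the real healthy covariance; silhouette-matched
synthetic classes are single-mode Gaussian shifts, whereas real
pathologies (back pain, spinal fusion, osteoarthritis) deform posture in
correlated, subject-specific ways; and the explainer's outputs have no
clinical ground truth. Green tests establish that the pipeline's
machinery — splitting, training, calibration, scoring, explanation —
behaves as specified on data of controlled difficulty.

## Numerical choices

- **OCSVM solver.** The dual QP (minimize ½αᵀKα on the capped simplex
  {0 ≤ α ≤ 1/(νn), Σα = 1}) is solved by accelerated projected gradient
  (FISTA) with gradient-based adaptive restart and a 64-step bisection
  projection; the step size is 1/‖K‖₂ from a deterministic power
  iteration. Solutions satisfy the KKT conditions to ~1e-3 relative
  tolerance on a few hundred samples in milliseconds. The offset ρ is the
  mean of (Kα) over margin support vectors; if none exist it is the
  midpoint of the KKT-feasible interval.
- **Degenerate-model guard.** A linear-kernel OCSVM on standardized
  (training-centered) data has the exact optimum w = 0: the origin lies
  inside the convex hull of the training points, so the decision function
  is constant and solver noise decides its sign. Such fits (RKHS norm
  αᵀKα below 1e-6 of the mean kernel diagonal) are excluded from the
  hyperparameter search — they can neither discriminate nor be
  calibrated. This is a structural property of the method, shared by any
  exact solver.
- **Platt scaling.** Univariate ridge-penalized logistic regression
  (IRLS), penalty strength chosen from {0.01, 0.1, 1, 10, 100} by 5-fold
  stratified cross-validated log loss on the calibration set. The score
  is standardized internally so the penalty is invariant to the
  decision function's arbitrary scale (small-`gamma` RBF scores span
  ~1e-4; without standardization every penalty level collapses the slope
  to zero). Reported intercept/slope are on the raw-score scale.
- **Random forest.** CART/Gini trees on bootstrap samples with
  mtry = ⌊√55⌋ = 7; leaf majority votes; deterministic given an integer
  seed (private mt19937, independent of R's RNG).
- **Isolation forest.** 100 trees, subsample 256, height limit
  ⌈log₂ψ⌉, anomaly score 2^(−E[h]/c(ψ)); the `contamination` fraction of
  highest-scoring samples is removed.
- **Explainer.** 2000 perturbations drawn from the fold's training
  feature distribution; exponential proximity kernel on standardized
  distance with width 0.75·√55; weights normalized to mean 1 so the
  ridge penalty of the surrogate keeps a fixed relative weight however
  far the instance lies from the perturbation cloud. The surrogate is a
  weighted ridge regression; the top-`n_features` (default 10) by
  absolute coefficient are refitted and reported as signed effects
  `coefficient × standardized displacement of the instance`, so positive
  effects push toward the outlier class for *this* instance. Weighted R²
  of the restricted surrogate is reported as fidelity; R² above 0.5 is
  expected for smooth, near-linear probability surfaces but not for
  saturated RBF-sigmoid surfaces in 55 dimensions, where a local linear
  model honestly explains less of the weighted variance.
- **Orderings.** Every subject/group ordering that feeds an RNG stream
  uses radix (C-locale) sorting, so results are independent of
  `LC_COLLATE`.

## Degenerate inputs and edge behavior

Constant features abort standardization and PCA with the feature named;
single-class calibration sets are rejected (they signal missing pathology
validation subjects); a constant probability function yields an all-zero
explanation with a degeneracy warning; cleaning that would empty the
cohort errors; silhouette bisection reports the best separation reached
if a target is unattainable in the search interval.

## Known limitations

- The one-class path's hyperparameter search sees only healthy validation
  subjects (that is the point of pathology independence), so it cannot
  distinguish two models that both accept all validation subjects but
  differ in how tightly they wrap the healthy class; ties fall to the
  smallest `nu`, i.e. the loosest boundary.
- With ~20 healthy subjects, per-fold test sets contain 4–5 healthy
  subjects; a single atypical subject moves a fold's MCC by ~0.2, so
  across-fold SDs of one-class metrics are intrinsically large at this
  cohort size.
- Silhouette separation is controlled in the standardized feature space;
  other spaces would give other centers for the same nominal silhouette.
- The explainer perturbs features independently; correlated-feature
  interactions are attributed linearly.
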