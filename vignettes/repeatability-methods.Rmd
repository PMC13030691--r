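---
title: "Methods: test–retest repeatability of PET lesion uptake features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test–retest repeatability of PET lesion uptake features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrep)
```

## The problem

Quantitative PET features — SUV~max~, SUV~mean~, SUV~total~ and lesion
volume — are used to stage disease and to call treatment response, but every
measurement carries noise from imaging physics, physiological fluctuation
and segmentation variability. A test–retest design separates that noise from
biology: the same patient is scanned twice within days, without intervening
therapy, so paired differences of matched lesions are pure measurement
variability. The question the analysis answers is *how large a change must
be before it exceeds that variability*, lesion by lesion.

`petrep` implements the full lesion-level analysis: feature extraction from
labeled SUV volumes, cross-timepoint lesion matching, log-ratio limits of
agreement with a variance estimator that respects the multiple-lesions-per-
patient structure, ICC and within-subject COV, and volume-threshold
stratification — plus a synthetic cohort generator that stands in for
clinical images, with recorded ground truth so the estimators can be tested
for parameter recovery.

## Model and estimators

### Log-ratio scale

Uptake features are positive and right-skewed, so all agreement statistics
work on $r_{ij} = \ln(x_{ij}^{\mathrm{retest}} / x_{ij}^{\mathrm{test}})$
for lesion $j$ of patient $i$. We fix the ratio direction as retest over
test; only the sign of the bias depends on this choice. Non-positive feature
values are a validation error naming the offending lesion, never a silent
drop.

### Limits of agreement with multiple lesions per patient

The 95% limits of agreement are back-transformed to percentages,

$$\text{95% LOA} = e^{\bar d - 1.96\sigma},\; e^{\bar d + 1.96\sigma},$$

with the multiplier fixed at 1.96 (a normal-theory interval, not a
$t$-quantile). $\bar d$ is the unweighted mean of $r$ over all lesions.
Lesions of one patient share a scan-to-scan bias (uptake-time differences,
injected-dose calibration, reconstruction), so the $r_{ij}$ are clustered
and $\sigma$ must pool a between-patient component with the within-patient
residual. With $n$ patients, $N$ lesions and $m_i$ lesions for patient $i$:

$$MS_b = \frac{\sum_i m_i(\bar r_i - \bar d)^2}{n-1},\qquad
  MS_w = \frac{\sum_{ij} (r_{ij} - \bar r_i)^2}{N-n},$$

$$m_0 = \frac{N - \sum_i m_i^2/N}{n-1},\qquad
  \hat\sigma_b^2 = \max\!\Big(0, \frac{MS_b - MS_w}{m_0}\Big),\qquad
  \sigma = \sqrt{\hat\sigma_b^2 + MS_w}.$$

The clamp at zero is standard method-of-moments practice. Two degenerate
groupings need a documented fallback: a single patient, and the
all-singleton case $N = n$ (no within-patient degrees of freedom). In both,
$\sigma$ collapses to the ordinary sample SD of $r$ (for $N = n$ this
follows automatically from setting $MS_w = 0$, since then $m_0 = 1$ and
$\hat\sigma_b^2 = \mathrm{var}(r)$).

### ICC and wCOV

The ICC is computed on **raw** feature values, with lesions as subjects and
the two scans as $k = 2$ repeated measurements, in the two-way
absolute-agreement single-measurement form

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$

A one-way random-effects variant is available via `icc(type = "one_way")`.
Raw values (rather than logs) were chosen because the ICC is meant to convey
how well lesions are distinguished on the scale clinicians read; the log
alternative is one flag away and both are oracle-tested.

The within-subject coefficient of variation uses the root-mean-square of
per-lesion CVs: within-pair SD $|x_1 - x_2|/\sqrt 2$ divided by the pair
mean, then $wCOV = 100\sqrt{\mathrm{mean}(CV^2)}$. A pooled-SD variant
(`wcov(method = "pooled_sd")`) divides the pooled within-pair SD by the
grand mean instead.

### Volume stratification

All metrics are recomputed after excluding small lesions, whose discrete-
voxel volume estimates are dominated by boundary effects. The default
thresholds are 1 and 1.5 cm³; a lesion is retained when its volume
*strictly* exceeds the threshold. A matched lesion has two volume estimates;
the mean of test and retest `volume_cc` is thresholded by default
(`volume_statistic = "test"` uses the test scan alone). All four features
share each stratum's lesion set.

### Lesion matching

Clinical pipelines match lesions across time points by image registration.
That machinery is not this package's contribution; `match_lesions()`
provides a transparent stand-in: greedy global-minimum matching of ROI
centroids (voxel-center convention), accepting pairs within
`max_distance_mm` (default 10 mm), with deterministic tie-breaking by label.
An optional pre-computed 4×4 affine can be applied to the retest centroids;
the default is the identity, appropriate for the synthetic pairs which share
a frame. Unmatched lesions are excluded from all downstream statistics.
One-to-one matching is imposed; split/merge events between scans are out of
scope.

## The synthetic cohort generator

No image data accompany the package, so `simulate_cohort()` generates
matched feature tables — and `simulate_phantom_pair()` voxelized image/mask
pairs — with the statistical structure the analysis assumes:

* true lesion volumes and uptakes are lognormal;
* each patient draws one bias $b_i \sim N(0, \tau^2)$ shared by all of their
  lesions and applied multiplicatively to every retest feature;
* each primitive feature (SUV~max~, SUV~mean~, volume) gets independent
  lognormal measurement noise with log-SD $\sigma_w$ per scan;
* SUV~total~ is `suv_mean * volume_cc` by construction at both time points,
  so it compounds the bias and the noise of both factors — which is why it
  is visibly the least repeatable feature in every report, matching clinical
  experience.

The multiplicative (log-normal) error model was chosen because the analysis
itself works on log-ratios: it makes the estimand analytically known. The
log-ratio of a primitive feature has SD $\sqrt{\tau^2 + 2\sigma_w^2}$ (two
independent noise draws plus the shared bias), which is what the
parameter-recovery tests assert. The bias is applied to the retest scan
only; splitting it across scans is equivalent up to sign and less
identifiable. Note that the per-lesion wCOV estimand under this generator is
$100\sqrt{\tau^2/2 + \sigma_w^2}$, because the patient bias enters every
pair difference; it reduces to $100\,\sigma_w$ only when $\tau = 0$.

Defaults were calibrated once to the cohort structure of published PSMA-PET
test–retest work: 22 patients averaging 13.5 lesions (about 300 matched
lesions); log-volume mean 0.57 and SD 1.55 (natural-log cm³), solving for a
lognormal in which ~64% of lesions exceed 1 cm³ and ~54% exceed 1.5 cm³;
log-uptake mean 1.6, SD 0.7 (median SUV~mean~ ≈ 5); $\tau = 0.10$ and
$\sigma_w = 0.09$, which put the SUV~max~ LOA near ±35% and its wCOV near
10%, the order reported for AI-segmented PSMA-PET lesions. With seed 1 the
default cohort yields 294 lesions, 187 above 1 cm³ and 160 above 1.5 cm³.

Seeding is split per patient (a derived seed per patient index), so
identical params and seed are bit-reproducible and enlarging the cohort
never perturbs earlier patients.

### Phantom mode

Phantoms place axis-aligned ellipsoids (random mild anisotropy with
volume-preserving axis factors) of uniform SUV plateau on a flat 0.1-SUV
background; the plateau carries the same bias/noise model as table mode, and
the ground truth (including the exact voxelized volume) is recorded. The
retest mask is the test mask with every boundary voxel (6-connectivity)
independently flipped — eroded or dilated — with probability
`jitter_boundary_prob`; each lesion always retains at least one voxel.
Because surface-to-volume ratio grows as lesions shrink, jitter perturbs
small-lesion volumes relatively more, reproducing qualitatively the
size-dependent repeatability the stratified analysis is designed to expose.
No partial-volume blur or scanner physics is simulated: keeping the plateau
and mask exact makes `extract_features()` on a noise-free phantom equal the
generator's intent *exactly*, which the tests assert. Lesion placement
retries up to `max_attempts` per lesion and raises a diagnostic placement
error if the grid cannot accommodate the draw.

What passing tests on this generator show — and what they do not: they
validate the estimators (parameter recovery, 95% coverage, oracle
equivalence) and the size-effect mechanism, on data satisfying the model's
assumptions. They cannot certify behaviour under model violations present in
real data: inter-feature noise correlation (only phantom mode induces it,
via the shared mask), partial-volume effects, reconstruction artefacts, or
imperfect registration.

## Numerical choices and edge cases

* `variance_components()` requires ≥ 2 lesions; strata with fewer than two
  pairs are skipped with a warning rather than an error.
* ICC with zero between-lesion variance is undefined and raises an error.
* Non-finite SUV voxels inside an ROI are treated as corrupt input (error),
  not excluded.
* Volume is reported in cm³ (1 cm³ = 1 mL); anisotropic voxels are
  supported, voxel volume = dx·dy·dz.
* Matching ties are broken by (smaller test label, smaller retest label);
  the procedure is fully deterministic.
* The pipeline's CSV/JSON outputs are byte-identical across runs with the
  same seed and config.

## Problem sizes used in the test suite

Monte-Carlo checks use cohorts of about 5 000 lesions (250 patients × 20
lesions) for moment recovery, wCOV recovery and LOA coverage; oracle
equivalence uses 200 random small datasets (≤ 6 patients × ≤ 5 lesions);
extraction exactness uses 100 randomized 16³ grids; matching recovery uses
50 jittered phantoms on 48³ grids; the size-effect check uses 20 phantom
cohorts on 56³ grids. These sizes keep Monte-Carlo error comfortably inside
the asserted tolerances.

## Known limitations

* No segmentation: label masks are inputs (clinically they come from an
  AI-assisted workflow with manual QA).
* No DICOM ingestion and no SUV computation from raw activity; inputs are
  already SUV-valued NIfTI volumes.
* Overlapping ROIs are not representable (disjoint integer labels required).
* No radiomic texture features, no patient-level aggregation, no
  response-assessment logic.
* The greedy centroid matcher is a documented simplification of
  registration-based tracking and is only claimed reliable for
  well-separated lesions.
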