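---
title: "Standardized T1w/T2w ratio mapping: models, simulation and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized T1w/T2w ratio mapping: models, simulation and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(st1t2ratio)
```

## The problem

The ratio of a T1-weighted over a co-registered T2-weighted structural MRI
volume (T1w/T2w) is widely used as a cheap proxy for white-matter
microstructural integrity: white matter is bright on T1w and dark on T2w,
so the ratio enhances tissue contrast while partially cancelling the
smooth multiplicative intensity inhomogeneity (bias field) shared by both
acquisitions. Its weakness is that raw T1w and T2w intensities are in
arbitrary scanner units: per-subject and per-scanner global gains do not
cancel in the plain ratio, inflating between-subject variability and
masking group effects, for example in the normal-appearing white matter
(NAWM) of people with relapsing-remitting multiple sclerosis (MS).

The standardized ratio removes this nuisance scale. With a scaling factor

$$ s = \frac{\operatorname{median}(\mathrm{T1w}\,|\,\mathrm{NAGM})}
           {\operatorname{median}(\mathrm{T2w}\,|\,\mathrm{NAGM})}, $$

the scaled T2w image is $\mathrm{sT2} = s\cdot \mathrm{T2w}$ and the
standardized ratio is

$$ \mathrm{sT1w/T2w} =
   \frac{\mathrm{T1w} - \mathrm{sT2}}{\mathrm{T1w} + \mathrm{sT2}}
   \in (-1, 1). $$

Normal-appearing gray matter (NAGM) maps to values near 0, white matter
into $(0, 1)$ and CSF into $(-1, 0)$. Because the scaling factor is a
ratio of medians of the same two images, any per-modality global gain
$a\cdot\mathrm{T1w}$, $b\cdot\mathrm{T2w}$ rescales $s$ by $a/b$ and
cancels exactly; this algebraic gain invariance is the package's core
claim and is tested to $10^{-10}$ relative tolerance. The reference
regions are *normal-appearing* tissue: lesion masks are subtracted from
the GM and WM masks before any median is taken, so focal lesion intensity
cannot leak into the scaling factor.

The package provides the full analysis as a tested pipeline: a synthetic
two-group MRI cohort generator, bias-field correction and lesion-aware
mask arithmetic, both ratio maps with per-tissue median extraction, and
the cohort statistics battery (coefficient-of-variation equality testing,
group comparisons, correlation, and backward-stepwise covariate models
with influence diagnostics).

## The synthetic cohort generator

No imaging data ship with the package; every downstream stage is
validated against a generator whose defaults encode the study conditions
of a 47 + 47 MS/control cohort:

* **Demographics.** 30 females per group; MS ages from a truncated normal
  with mean 37.69 and SD 9.22 years on [20, 64]; each control is the
  matched partner of one patient — identical sex, age within ±0.5 years.
* **Lesion load.** MS lesion counts from a moment-matched negative
  binomial (mean 59.23, SD 46.75 — strongly overdispersed, hence not
  Poisson; a Poisson fallback covers variance ≤ mean), controls 3.09
  (3.58); total lesion volumes from moment-matched lognormals (MS 5.07 ml,
  SD 6.86; controls 0.07, 0.09), zero exactly when the count is zero, and
  capped at 40 ml so a heavy-tail draw cannot exceed the phantom's white
  matter. EDSS is drawn on the 0.5 grid in [0, 6] (median ≈ 2), disease
  duration from a lognormal matched to 24.6 (57.57) months; both exist
  only for patients.
* **Head size.** A unitless scaling factor (the analog of a volumetric
  standard-space normalisation factor, larger = smaller head) from
  sex-specific normals (females 1.30, males 1.18, SD 0.05); it modulates
  the phantom radii as scale$^{-1/3}$. By default one random subject's
  value is blanked, so covariate models containing head-size terms lose
  one complete case — reproducing the 93-vs-94 observation-count pattern
  that listwise deletion produces along a stepwise path.
* **Geometry.** An ellipsoidal brain with a central CSF core, a WM
  interior and a GM shell on a configurable grid (default 64³ at 2 mm —
  coarse relative to clinical 1 mm whole-head acquisitions, but medians
  over thousands of voxels are insensitive to resolution and the cohort
  stays fast). Lesions are compact blobs grown voxel-exact inside deep
  WM until the subject's total lesion volume is met (up to voxel
  rounding), so the emitted mask reproduces the requested load within a
  few voxels.
* **Intensities.** Tissue means (arbitrary units) T1w: CSF 150, GM 300,
  lesion 350; T2w: CSF 200, GM 60, WM 40, lesion 70 — lesions are
  T2w-hyperintense and T1w-hypointense. The WM T1w mean is *not* a free
  parameter: each subject's target NAWM standardized median
  $s^\* = 0.41 - 0.02\,[\mathrm{MS}] - 0.001\,(\mathrm{age}-\bar{a})
  - 0.0004\,\mathrm{count}$ is implanted by setting it to
  $w(1+s^\*)/(1-s^\*)$, where $w$ is the noise-free scaled-T2w WM value.
  Implanting through T1w keeps the T2w NAGM anchor group-neutral, which
  matches the empirical observation that raw NAGM values do not separate
  the groups. Baseline and effect sizes default to the magnitudes of the
  published covariate models.
* **Nuisance processes.** Per-subject, per-modality lognormal gains
  (SD 0.12 on the log scale — chosen so the plain-ratio NAWM medians show
  a between-subject CoV near the reported 17–22%), an independent smooth
  multiplicative bias field per modality (exponentiated random degree-2
  polynomial, ≤ 20% fractional deviation inside the brain, mean 1), and
  additive Gaussian noise (SD 2 intensity units). Gaussian rather than
  Rician noise is a deliberate simplification: at the tissue SNRs
  involved (≈ 20 and above) the Rician bias of the median is negligible,
  and Gaussian noise keeps the implanted medians exactly centred.

Everything is deterministic given the master seed: per-subject streams
are derived by hashing the seed with the subject id and stage name, so
any subject can be regenerated in isolation and full reruns are
byte-identical.

What the phantom does *not* emulate — folded cortical geometry, partial
volume at tissue borders, multi-site field-strength differences, FLAIR
contrast — bounds what passing tests show: they validate the estimators
and the statistical battery under the stated generative model, not the
segmentation or registration behaviour of any real-scan pipeline (both
are out of scope; inputs are assumed co-registered on one grid, and a
grid mismatch is a hard error rather than a resampling trigger).

## Bias-field correction

The multiplicative inhomogeneity is modelled as the exponential of a 3D
polynomial (default total degree 2, a command-line flag) in normalised
grid coordinates. The estimator works in the *gradient domain*: for every
pair of adjacent brain voxels, the difference of log intensities equals
the difference of the log field whenever both voxels lie in the same
tissue; pairs straddling a tissue boundary are sparse, gross outliers. A
trimmed least-squares fit (retaining the best 80% of pairs, iterated
until the retained set stabilises, then refined on all pairs within 2.5
robust SDs) therefore recovers the polynomial coefficients without
absorbing anatomical contrast.

The obvious alternative — least squares on the log *intensities*
directly — fails here in an instructive way: the phantom's radial
anatomy (log-intensity steps of 0.4–1.6 between tissues) projects
strongly onto a degree-2 basis, so the fitted "field" soaks up anatomy
and corrupts downstream medians by 0.1–0.2 in standardized-ratio units.
Robust intensity-domain variants (least trimmed squares over voxels)
remove the projection only when the trimmed selection lands on a single
tissue class, which is basin-dependent and unreliable; the
gradient-domain formulation has no such basin structure because the
anatomy is a sparse outlier set rather than a dense signal. On noiseless
phantoms the generating field is recovered to machine precision, and
under the default noise the NAWM standardized median is recovered to
about 0.002.

The constant term is unidentified in the gradient domain and is pinned by
the output contract: the returned field has mean exactly 1 over the brain
mask, so correction never changes the global scale of an image. Voxels
that are non-positive inside the brain are excluded from the fit and
reported, never clamped. Correction divides by the field inside the brain
and passes everything outside through unchanged. Each modality gets its
own field (nothing guarantees T1w and T2w share inhomogeneity, and the
generator draws them independently).

## Ratio maps and medians

Both maps are computed inside the brain mask with a denominator guard:
voxels where the denominator (T2w for the plain ratio, T1w + sT2 for the
standardized one) is at or below $10^{-6}\times$ the median brain value
of that denominator are excluded from the valid mask rather than
producing unbounded values. All medians — including the scaling factor's
NAGM medians — use the midpoint-of-two convention for even counts (R's
default), stated for bit-reproducibility. Tissue medians are extracted
for four measures (T1w, T2w, plain ratio, standardized ratio) in three
regions (NAGM, NAWM, CSF), on the bias-corrected volumes throughout so
that all four measures see identical preprocessing.

## The statistics battery

* **Between-subject variability.** The coefficient of variation
  (100·SD/mean, n−1 denominator) of the per-subject NAWM medians, per
  group and measure. Equality of CoVs is tested with the asymptotic
  chi-square statistic
  $D = \sum_i m_i (c_i - \bar c)^2 \,/\, [\bar c^2(0.5 + \bar c^2)]$,
  $m_i = n_i - 1$, $\bar c = \sum m_i c_i / \sum m_i$, on $k-1$ degrees
  of freedom. The implementation is cross-validated by a Monte-Carlo
  calibration oracle (2000 null replicates at n = 47 + 47, true CoV 0.15:
  empirical size must lie in [0.035, 0.065]). The two measures being
  compared come from the same subjects; treating them as independent
  samples replicates the source analysis and is a documented
  fidelity-over-optimality choice.
* **Group comparisons.** Welch t-tests (from raw values, and from summary
  statistics for published-table reproduction) in HC-minus-MS order,
  chi-square without continuity correction for sex, Pearson correlation
  with the adjusted R² of the simple linear fit. The family-wise gate for
  all final inference is the Bonferroni-corrected p < 0.004; two-sided
  throughout.
* **Covariate models.** Ordinary least squares with backward elimination:
  fit the full model, repeatedly drop the term whose worst coefficient
  p-value is largest (if ≥ 0.05), refit, stop when every term is
  significant. Sex never enters on its own, only as a sex-by-head-size
  interaction (one coefficient per sex, no main effect), and such
  multi-coefficient terms are kept or dropped as a unit. Marginality is
  respected — a main effect is not removable while a retained interaction
  contains it. Every model along the path is refitted on the complete
  cases of its own variables, so observation counts can grow as a
  missing-valued covariate drops out. Each model's AIC is recorded and
  the minimum-AIC model is selected; the removal threshold is the
  conventional 0.05, not the Bonferroni level, which applies to final
  inference only. Maximum Cook's distance is recorded for every model and
  values above 1 are flagged.

The whole-cohort models regress each NAWM measure on group, age and
sex-by-head-size; the patient-only models on age, disease duration, EDSS,
lesion volume, lesion count, age-by-duration and sex-by-head-size. The
parameter-recovery validation additionally fits the generator's true
design (group, age, lesion count, sex-by-head-size) directly, since
lesion count is not part of the whole-cohort analog but is needed to
identify the implanted per-lesion slope.

## Numerical and design choices

* **Removal vs selection on noise.** On a pure-noise response, backward
  elimination reaches the intercept-only model in ≈ 85% of replicates
  (the last surviving term is the minimum of several p-values, so its
  chance of crossing 0.05 exceeds the nominal level), while min-AIC
  selection keeps a noise term whenever its $t^2 > 2$ (≈ 40% for three
  candidates). The suite asserts the elimination-endpoint property; the
  selection rule is AIC by contract.
* **Degenerate inputs.** Empty normal-appearing masks, regions with no
  valid voxels, non-positive NAGM medians, non-positive scaling factors,
  rank-deficient designs, underdetermined bias fits and infeasible lesion
  loads are hard errors carrying the subject and stage, never silent
  repairs.
* **Problem sizes.** Cohort-level validations run at 32³ (3 mm voxels,
  so the phantom WM ≈ 90 ml comfortably exceeds the 40 ml lesion cap):
  20 seeds at n = 47 + 47 for the CoV-reduction property and 10 seeds at
  n = 200 + 200 for parameter recovery. The recovery runs disable the
  bias field: the corrector's small residual anatomy flattening varies
  with lesion load and would otherwise confound the −0.0004/lesion slope
  it shares a scale with; field recovery has its own contract tests.
* **Group order.** The printed negative age t-statistic corresponds to
  HC − MS; the report records the order explicitly rather than guessing.
* **Healthy-control hyperintensities.** Their morphology is not
  specified anywhere; the generator treats them exactly like MS lesions
  with the control moments (3.09 counts, 0.07 ml), which is the neutral
  choice and keeps the control NAWM definition symmetric.

## Known limitations

The phantom's piecewise-constant tissues make bias estimation easier than
on real brains (no partial volume, no intra-tissue texture); the
machine-precision field recovery should be read as a contract check, not
a claim about clinical data. The CoV comparison inherits the
independent-samples approximation discussed above. Registration, skull
stripping, lesion segmentation and real-scanner effects (Rician noise,
multi-site gains beyond a global factor) are explicitly out of scope.

## Reproducing the full analysis

```{r, eval = FALSE}
cfg <- generatorConfig(seed = 1L)        # 47 + 47 study conditions
report <- runCohortPipeline(cfg, outDir = "run1")
report                                   # CoV table, tests, group effects
selectedModel(report@stepwiseCohort[["st1t2_NAWM"]])
```

`scripts/acceptance.R` recomputes the headline quantities from scratch
(published-summary statistics, a full synthetic cohort's CoV table and
equality tests, the NAWM group comparison and the recovered covariate
model) and writes them as JSON; see the README.
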