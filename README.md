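# st1t2ratio

Standardized T1w/T2w ratio mapping of normal-appearing white matter
(NAWM), as a fully tested simulation-and-analysis pipeline in R.

## The problem

The voxelwise ratio of a T1-weighted over a co-registered T2-weighted
structural MRI volume (T1w/T2w) is a convenient proxy for white-matter
microstructural integrity, but raw T1w and T2w intensities carry
arbitrary per-subject and per-scanner scale factors that do **not**
cancel in the plain ratio. The standardized variant removes them: with a
scaling factor

    s = median(T1w | NAGM) / median(T2w | NAGM),      sT2 = s * T2w

the standardized ratio is

    sT1w/T2w = (T1w - sT2) / (T1w + sT2)  in (-1, 1)

where NAGM (normal-appearing gray matter) is the gray-matter mask with
lesions subtracted. Gray matter maps near 0, white matter into (0, 1),
CSF into (-1, 0), and independent global gains on T1w and T2w cancel
exactly. The package implements this mapping and everything needed to
validate it end to end without any external data:

* **Synthetic cohort generator** — a two-group (MS / healthy control)
  cohort of tissue-label phantoms and T1w/T2w volumes with per-subject
  scanner gains, smooth bias fields, focal white-matter lesions and a
  demographic/clinical subject table, with implanted NAWM effects
  (diagnosis, age, lesion count).
* **Preprocessing** — polynomial bias-field estimation (robust
  gradient-domain fit) and correction; lesion-aware NAGM/NAWM mask
  arithmetic; NIfTI-1 I/O.
* **Ratio mapping** — scaling factor, both ratio maps with denominator
  guards, per-tissue median extraction.
* **Cohort statistics** — coefficient of variation and its asymptotic
  equality test (chi-square), Welch t-tests (raw and from summary
  statistics), chi-square and Pearson helpers, backward-stepwise OLS
  covariate models with AIC selection and Cook's-distance diagnostics,
  with a Bonferroni significance gate (p < 0.004) for final inference.

It is intended for researchers evaluating intensity-standardization
methods for structural MRI, and as a reference implementation of the
sT1w/T2w analysis chain.

## Worked example

```r
library(st1t2ratio)

cfg <- generatorConfig(gridShape = 32L, voxelSizeMM = 3, seed = 1L)
report <- runCohortPipeline(cfg)   # 47 + 47 subjects, ~15 s
report
```

```
CohortReport: 47 MS / 47 HC subjects
NAWM coefficient of variation (%):
 group measure cov_percent
    MS    t1t2   16.659448
    HC    t1t2   18.088545
    MS   st1t2    5.269928
    HC   st1t2    2.421853
  CoV equality (MS): chi-sq = 48.47, df = 1, p = 3.36e-12
  CoV equality (HC): chi-sq = 105.14, df = 1, p = 1.14e-24
Group differences passing Bonferroni gate (p < 0.004): T1w NAWM, st1t2 NAWM
```

Reading: standardization cuts the between-subject CoV of the NAWM
medians from ~17–18% to ~2–5% in both groups, and the equality test
rejects overwhelmingly — the plain ratio's variability is dominated by
scanner gains, which the standardized ratio cancels. The group contrast
implanted by the generator (MS diagnosis −0.02, age −0.001/yr, lesions
−0.0004/lesion on the NAWM standardized median) is detected in the
standardized NAWM values and recovered by the covariate model:

```r
sw <- report@stepwiseCohort[["st1t2_NAWM"]]
sw
#> StepwiseFit for 'st1t2_NAWM': 2 model(s), removal threshold p < 0.05
#>   [1] ~ group + age + sex:head_size_scale | n=93 adjR2=0.807 AIC=-570.73 maxCook=0.221
#>   [2] ~ group + age | n=94 adjR2=0.810 AIC=-579.83 maxCook=0.277 <- selected (min AIC)
```

(The raw T1w NAWM difference is also visible under this generator
because the implant acts through the WM T1w mean; at realistic gain
variability it washes out while the standardized contrast survives —
see the methods vignette.)

Per-subject processing is available piecewise: `generateSubjectTable()`,
`generateLabelVolume()`, `renderIntensityVolumes()`,
`estimateBiasField()` / `correctBias()`, `computeRatioMaps()`,
`extractTissueMedians()`; `simulateCohort()` writes NIfTI volumes, and
`inst/cli/st1t2.R` exposes `simulate` / `preprocess` / `ratio` /
`stats` / `run-all` subcommands for shell use.

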