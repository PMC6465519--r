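#' @import methods
NULL

MODALITIES <- c("T1w", "T2w", "ratio", "st_ratio", "field")
TISSUES <- c("csf", "gm", "wm", "lesion")

#' Configuration for the synthetic MRI cohort generator
#'
#' Bundles every parameter of the synthetic two-group (MS / healthy control)
#' cohort: phantom geometry, tissue intensity means for the T1w and T2w
#' contrasts, per-subject scanner gain and bias-field nuisance magnitudes,
#' additive noise, demographic and lesion-load distributions, and the
#' effect sizes implanted into the normal-appearing white matter (NAWM)
#' standardized ratio.
#'
#' @slot gridShape integer(3); voxels per axis (each >= 16).
#' @slot voxelSizeMM scalar; isotropic voxel edge length in mm.
#' @slot tissueMeansT1w,tissueMeansT2w named numeric over
#'   `c("csf","gm","wm","lesion")`; noise-free tissue intensity means in
#'   arbitrary scanner units. The WM T1w mean is a nominal value only: the
#'   renderer overrides it to implant the per-subject target NAWM
#'   standardized-ratio median (see [renderIntensityVolumes()]).
#' @slot gainSdT1w,gainSdT2w SD of the per-subject log gain for each
#'   modality (unitless; 0 disables gains).
#' @slot noiseSd additive Gaussian noise SD, intensity units.
#' @slot biasAmplitude maximum fractional deviation of the multiplicative
#'   bias field inside the brain, in [0, 0.5).
#' @slot nPerGroup subjects per group (>= 2).
#' @slot stBaseline baseline NAWM standardized-ratio median for a healthy
#'   control of mean age with zero lesions.
#' @slot effectMS additive shift of the NAWM standardized-ratio median for
#'   the MS group.
#' @slot effectAge slope per year of age (age centred at `ageMean`).
#' @slot effectLesionCount slope per T2 lesion.
#' @slot lesionCountMoments,lesionVolumeMoments 2x2 numeric matrices,
#'   rows `ms`/`hc`, columns `mean`/`sd`; lesion count moments feed a
#'   moment-matched negative binomial, volume moments (ml) a lognormal.
#' @slot lesionVolumeMax cap (ml) applied to lesion-volume draws so that a
#'   heavy-tail draw cannot exceed the phantom's white matter.
#' @slot ageMean,ageSd,ageRange truncated-normal age distribution (years).
#' @slot femaleCount females per group.
#' @slot edssMean,edssSd,edssRange truncated-normal EDSS distribution,
#'   rounded to the 0.5 grid (patients only).
#' @slot durationMoments mean/sd of disease duration in months (lognormal).
#' @slot headSizeMeanF,headSizeMeanM,headSizeSd normal head-size scaling
#'   factor by sex (analog of a SIENAX volumetric scaling factor; larger
#'   values mean smaller heads).
#' @slot missingHeadSize if TRUE, one randomly chosen subject's head-size
#'   scale is blanked, so covariate models with head-size terms lose one
#'   complete case.
#' @slot seed integer master seed; all per-subject randomness is derived
#'   from it deterministically.
#' @seealso [generatorConfig()] for construction with defaults.
#' @export
setClass("GeneratorConfig", representation(
  gridShape = "integer",
  voxelSizeMM = "numeric",
  tissueMeansT1w = "numeric",
  tissueMeansT2w = "numeric",
  gainSdT1w = "numeric",
  gainSdT2w = "numeric",
  noiseSd = "numeric",
  biasAmplitude = "numeric",
  nPerGroup = "integer",
  stBaseline = "numeric",
  effectMS = "numeric",
  effectAge = "numeric",
  effectLesionCount = "numeric",
  lesionCountMoments = "matrix",
  lesionVolumeMoments = "matrix",
  lesionVolumeMax = "numeric",
  ageMean = "numeric",
  ageSd = "numeric",
  ageRange = "numeric",
  femaleCount = "integer",
  edssMean = "numeric",
  edssSd = "numeric",
  edssRange = "numeric",
  durationMoments = "numeric",
  headSizeMeanF = "numeric",
  headSizeMeanM = "numeric",
  headSizeSd = "numeric",
  missingHeadSize = "logical",
  seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
    msg <- c(msg, "gridShape must be three integers, each >= 16")
  if (object@voxelSizeMM <= 0) msg <- c(msg, "voxelSizeMM must be > 0")
  for (s in c("tissueMeansT1w", "tissueMeansT2w")) {
    v <- slot(object, s)
    if (!all(TISSUES %in% names(v)) || any(v <= 0))
      msg <- c(msg, sprintf("%s must be positive and named over %s", s,
                            paste(TISSUES, collapse = ", ")))
  }
  if (object@gainSdT1w < 0 || object@gainSdT2w < 0)
    msg <- c(msg, "gain SDs must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 0.5)
    msg <- c(msg, "biasAmplitude must lie in [0, 0.5)")
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@femaleCount < 0L || object@femaleCount > object@nPerGroup)
    msg <- c(msg, "femaleCount must be between 0 and nPerGroup")
  for (s in c("lesionCountMoments", "lesionVolumeMoments")) {
    m <- slot(object, s)
    if (!identical(dim(m), c(2L, 2L)) ||
        !identical(rownames(m), c("ms", "hc")) ||
        !identical(colnames(m), c("mean", "sd")) || any(m < 0))
      msg <- c(msg, sprintf("%s must be a non-negative 2x2 matrix (ms/hc x mean/sd)", s))
  }
  if (diff(object@ageRange) <= 0) msg <- c(msg, "ageRange must be increasing")
  if (length(msg)) msg else TRUE
})

#' One 3D scalar MRI volume on a fixed grid
#'
#' @slot values 3D numeric array (finite; raw modalities non-negative).
#' @slot voxelSizeMM isotropic voxel edge length in mm.
#' @slot modality one of `"T1w"`, `"T2w"`, `"ratio"`, `"st_ratio"`, `"field"`.
#' @export
setClass("ImageVolume", representation(
  values = "array",
  voxelSizeMM = "numeric",
  modality = "character"
))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all voxel values must be finite")
  if (!object@modality %in% MODALITIES)
    msg <- c(msg, paste("modality must be one of", paste(MODALITIES, collapse = ", ")))
  if (object@modality %in% c("T1w", "T2w") && any(object@values < 0))
    msg <- c(msg, "raw-modality values must be >= 0")
  if (object@voxelSizeMM <= 0) msg <- c(msg, "voxelSizeMM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Tissue mask set for one subject
#'
#' Boolean brain, gray matter (GM), white matter (WM), CSF and lesion
#' volumes on one grid, plus the derived normal-appearing masks
#' NAGM = GM \\ lesion and NAWM = WM \\ lesion (populated by
#' [makeNAMasks()]). GM, WM and CSF are pairwise disjoint subsets of the
#' brain mask; lesions are contained in the brain mask. By the label
#' convention used throughout, WM includes lesion voxels (lesions arise
#' within white matter), so the lesion subtraction is meaningful.
#'
#' @slot brain,gm,wm,csf,lesion logical 3D arrays on a shared grid.
#' @slot nagm,nawm derived logical arrays (length-0 until populated).
#' @export
setClass("TissueMaskSet", representation(
  brain = "array", gm = "array", wm = "array", csf = "array",
  lesion = "array", nagm = "array", nawm = "array"
))

setValidity("TissueMaskSet", function(object) {
  msg <- character()
  base <- c("brain", "gm", "wm", "csf", "lesion")
  dims <- lapply(base, function(s) dim(slot(object, s)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    msg <- c(msg, "all base masks must share one grid")
  for (s in c(base, "nagm", "nawm")) {
    v <- slot(object, s)
    if (length(v) && !is.logical(v)) msg <- c(msg, paste(s, "must be logical"))
  }
  if (!length(msg)) {
    b <- object@brain
    if (any(object@gm & object@csf) || any(object@wm & object@csf))
      msg <- c(msg, "gm, wm, csf must be pairwise disjoint")
    # note: wm may include gm? no — disjointness includes gm&wm
    if (any(object@gm & object@wm))
      msg <- c(msg, "gm and wm must be disjoint")
    for (s in c("gm", "wm", "csf", "lesion"))
      if (any(slot(object, s) & !b))
        msg <- c(msg, paste(s, "must be contained in brain"))
    if (length(object@nagm)) {
      if (!identical(object@nagm, object@gm & !object@lesion))
        msg <- c(msg, "nagm must equal gm AND NOT lesion")
      if (!identical(object@nawm, object@wm & !object@lesion))
        msg <- c(msg, "nawm must equal wm AND NOT lesion")
      if (!any(object@nagm) || !any(object@nawm))
        msg <- c(msg, "nagm and nawm must be non-empty")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ratio maps for one subject
#'
#' Holds the classic T1w/T2w ratio map, the standardized
#' (T1w - sT2)/(T1w + sT2) map, the NAGM-derived scaling factor, and the
#' mask of voxels where both maps are defined (denominator guards not
#' fired).
#'
#' @slot t1t2,st1t2 3D numeric arrays (NA outside `validMask`).
#' @slot scalingFactor positive scalar: median NAGM T1w / median NAGM T2w.
#' @slot validMask logical 3D array.
#' @slot voxelSizeMM voxel edge length in mm.
#' @export
setClass("RatioMaps", representation(
  t1t2 = "array", st1t2 = "array",
  scalingFactor = "numeric", validMask = "array", voxelSizeMM = "numeric"
))

setValidity("RatioMaps", function(object) {
  msg <- character()
  if (length(object@scalingFactor) && object@scalingFactor <= 0)
    msg <- c(msg, "scalingFactor must be > 0")
  if (length(object@st1t2)) {
    v <- object@st1t2[object@validMask]
    if (length(v) && any(abs(v) >= 1))
      msg <- c(msg, "standardized ratio must lie strictly inside (-1, 1) on valid voxels")
  }
  if (length(msg)) msg else TRUE
})

#' Backward-stepwise OLS model path
#'
#' The ordered sequence of ordinary-least-squares fits visited by backward
#' elimination, each recorded with its terms, coefficients and p-values,
#' adjusted R-squared, residual SE, F statistic, AIC, observation count and
#' maximum Cook's distance; `selected` indexes the minimum-AIC model.
#'
#' @slot response character; modelled response column.
#' @slot path list of per-model records (see [backwardStepwiseOLS()]).
#' @slot selected integer index of the minimum-AIC model in `path`.
#' @slot threshold removal p-value threshold used during elimination.
#' @export
setClass("StepwiseFit", representation(
  response = "character", path = "list", selected = "integer",
  threshold = "numeric"
))

setValidity("StepwiseFit", function(object) {
  msg <- character()
  aics <- vapply(object@path, function(m) m$aic, numeric(1))
  if (!all(is.finite(aics))) msg <- c(msg, "every model AIC must be finite")
  if (length(aics) &&
      (object@selected < 1L || object@selected > length(aics) ||
       aics[object@selected] > min(aics) + 1e-8))
    msg <- c(msg, "selected model must attain the minimum AIC")
  if (length(msg)) msg else TRUE
})

#' Full cohort analysis report
#'
#' @slot subjects subject table (demographics, clinical covariates).
#' @slot medians long per-subject tissue-median table
#'   (subject_id, measure, region, median).
#' @slot demographics age Welch t-test and sex chi-square results.
#' @slot covTable per group x measure NAWM coefficient of variation (%).
#' @slot covTests per-group CoV-equality (asymptotic chi-square) results.
#' @slot groupComparisons Welch t-tests per measure x region with the
#'   Bonferroni significance gate applied.
#' @slot correlation Pearson r and adjusted R-squared between the two NAWM
#'   ratio measures.
#' @slot stepwiseCohort,stepwisePatients lists of [StepwiseFit-class]
#'   objects for the whole-cohort and patient-only NAWM covariate models.
#' @slot settings list echoing the analysis settings (seed, thresholds,
#'   stage toggles, group order used in differences).
#' @export
setClass("CohortReport", representation(
  subjects = "data.frame", medians = "data.frame",
  demographics = "list", covTable = "data.frame", covTests = "list",
  groupComparisons = "data.frame", correlation = "list",
  stepwiseCohort = "list", stepwisePatients = "list", settings = "list"
))
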