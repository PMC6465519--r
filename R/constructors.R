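#' Build a generator configuration
#'
#' Returns a [GeneratorConfig-class] populated with the study-condition
#' defaults: a 47 + 47 two-group cohort (30 females per group), ages
#' 37.69 (9.22) years truncated to roughly 20-64, MS lesion counts
#' moment-matched to 59.23 (46.75) with volumes 5.07 (6.86) ml, healthy
#' controls 3.09 (3.58) and 0.07 (0.09) ml, and NAWM standardized-ratio
#' effects of -0.02 for MS diagnosis, -0.001 per year of age and -0.0004
#' per lesion around a baseline median of 0.41.
#'
#' @param gridShape voxels per axis (length 1 or 3).
#' @param voxelSizeMM isotropic voxel size, mm.
#' @param tissueMeansT1w,tissueMeansT2w named tissue intensity means
#'   (`csf`, `gm`, `wm`, `lesion`), arbitrary units.
#' @param gainSdT1w,gainSdT2w SD of per-subject log gains.
#' @param noiseSd additive Gaussian noise SD.
#' @param biasAmplitude max fractional bias-field deviation, in [0, 0.5).
#' @param nPerGroup subjects per group.
#' @param stBaseline,effectMS,effectAge,effectLesionCount implanted NAWM
#'   standardized-ratio baseline and effects.
#' @param lesionCountMoments,lesionVolumeMoments 2x2 matrices (rows
#'   `ms`, `hc`; columns `mean`, `sd`).
#' @param lesionVolumeMax cap on lesion volume draws, ml.
#' @param ageMean,ageSd,ageRange age distribution, years.
#' @param femaleCount females per group.
#' @param edssMean,edssSd,edssRange EDSS distribution (0.5 grid).
#' @param durationMoments disease duration mean/sd, months.
#' @param headSizeMeanF,headSizeMeanM,headSizeSd head-size scaling factor
#'   distribution by sex.
#' @param missingHeadSize blank one subject's head-size scale if TRUE.
#' @param seed integer master seed.
#' @return a validated [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(nPerGroup = 4L, gridShape = 24L, seed = 1L)
#' @export
generatorConfig <- function(
    gridShape = 64L,
    voxelSizeMM = 2.0,
    tissueMeansT1w = c(csf = 150, gm = 300, wm = 430, lesion = 350),
    tissueMeansT2w = c(csf = 200, gm = 60, wm = 40, lesion = 70),
    gainSdT1w = 0.12,
    gainSdT2w = 0.12,
    noiseSd = 2.0,
    biasAmplitude = 0.2,
    nPerGroup = 47L,
    stBaseline = 0.41,
    effectMS = -0.02,
    effectAge = -0.001,
    effectLesionCount = -0.0004,
    lesionCountMoments = rbind(ms = c(mean = 59.23, sd = 46.75),
                               hc = c(mean = 3.09, sd = 3.58)),
    lesionVolumeMoments = rbind(ms = c(mean = 5.07, sd = 6.86),
                                hc = c(mean = 0.07, sd = 0.09)),
    lesionVolumeMax = 40,
    ageMean = 37.69,
    ageSd = 9.22,
    ageRange = c(20, 64),
    femaleCount = 30L,
    edssMean = 2.0,
    edssSd = 1.5,
    edssRange = c(0, 6),
    durationMoments = c(mean = 24.6, sd = 57.57),
    headSizeMeanF = 1.30,
    headSizeMeanM = 1.18,
    headSizeSd = 0.05,
    missingHeadSize = TRUE,
    seed = 20190334L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  nPerGroup <- as.integer(nPerGroup)
  if (femaleCount > nPerGroup) femaleCount <- nPerGroup
  new("GeneratorConfig",
      gridShape = as.integer(gridShape), voxelSizeMM = voxelSizeMM,
      tissueMeansT1w = tissueMeansT1w, tissueMeansT2w = tissueMeansT2w,
      gainSdT1w = gainSdT1w, gainSdT2w = gainSdT2w, noiseSd = noiseSd,
      biasAmplitude = biasAmplitude, nPerGroup = nPerGroup,
      stBaseline = stBaseline, effectMS = effectMS, effectAge = effectAge,
      effectLesionCount = effectLesionCount,
      lesionCountMoments = lesionCountMoments,
      lesionVolumeMoments = lesionVolumeMoments,
      lesionVolumeMax = lesionVolumeMax,
      ageMean = ageMean, ageSd = ageSd, ageRange = ageRange,
      femaleCount = as.integer(femaleCount),
      edssMean = edssMean, edssSd = edssSd, edssRange = edssRange,
      durationMoments = durationMoments,
      headSizeMeanF = headSizeMeanF, headSizeMeanM = headSizeMeanM,
      headSizeSd = headSizeSd, missingHeadSize = missingHeadSize,
      seed = as.integer(seed))
}

#' Construct an ImageVolume
#'
#' @param values 3D numeric array.
#' @param voxelSizeMM voxel edge length, mm.
#' @param modality one of `"T1w"`, `"T2w"`, `"ratio"`, `"st_ratio"`,
#'   `"field"`.
#' @return an [ImageVolume-class] object.
#' @export
imageVolume <- function(values, voxelSizeMM, modality) {
  new("ImageVolume", values = values, voxelSizeMM = voxelSizeMM,
      modality = modality)
}

#' Construct a TissueMaskSet from base masks
#'
#' The derived NAGM/NAWM masks are left unpopulated; call [makeNAMasks()].
#'
#' @param brain,gm,wm,csf,lesion logical 3D arrays on one grid.
#' @return a [TissueMaskSet-class] object.
#' @export
tissueMaskSet <- function(brain, gm, wm, csf, lesion) {
  new("TissueMaskSet", brain = brain, gm = gm, wm = wm, csf = csf,
      lesion = lesion,
      nagm = array(logical(0), dim = c(0L, 0L, 0L)),
      nawm = array(logical(0), dim = c(0L, 0L, 0L)))
}
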