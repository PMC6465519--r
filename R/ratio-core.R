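## T1w/T2w ratio, standardized ratio, and per-tissue median extraction.

defaultEps <- function(denominator, brain) {
  1e-6 * median(denominator[brain])
}

#' Compute the NAGM-based scaling factor
#'
#' The scaling factor is the median NAGM (lesion-excluded gray matter)
#' intensity in the T1w image divided by the median NAGM intensity in the
#' T2w image; multiplying the T2w image by it yields the scaled T2w (sT2)
#' whose gray-matter level matches the T1w image.
#'
#' @param t1w,t2w [ImageVolume-class] objects on one grid.
#' @param nagm logical NAGM mask (non-empty).
#' @return a positive scalar.
#' @examples
#' dims <- c(4L, 4L, 4L)
#' m <- array(TRUE, dims)
#' computeScalingFactor(imageVolume(array(300, dims), 1, "T1w"),
#'                      imageVolume(array(60, dims), 1, "T2w"), m)  # 5
#' @export
computeScalingFactor <- function(t1w, t2w, nagm) {
  stopifnot(identical(dim(t1w@values), dim(t2w@values)),
            identical(dim(t1w@values), dim(nagm)))
  if (!any(nagm)) stop("empty NAGM mask")
  m1 <- maskedMedian(t1w@values, nagm)
  m2 <- maskedMedian(t2w@values, nagm)
  if (m1 <= 0 || m2 <= 0)
    stop("corrupt input: non-positive NAGM median intensity")
  m1 / m2
}

#' Compute the classic T1w/T2w ratio map
#'
#' Voxelwise T1w / T2w inside the brain; voxels whose T2w value is at or
#' below the denominator guard `eps` are excluded from the valid mask
#' rather than producing unbounded values.
#'
#' @param t1w,t2w [ImageVolume-class] objects on one grid.
#' @param brain logical brain mask.
#' @param eps denominator guard; default `1e-6 *` median brain T2w.
#' @return a [RatioMaps-class] with the `t1t2` map and `validMask` set.
#' @export
computeT1T2Ratio <- function(t1w, t2w, brain, eps = NULL) {
  stopifnot(identical(dim(t1w@values), dim(t2w@values)),
            identical(dim(t1w@values), dim(brain)))
  if (is.null(eps)) eps <- defaultEps(t2w@values, brain)
  valid <- brain & t2w@values > eps
  out <- array(NA_real_, dim(t1w@values))
  out[valid] <- t1w@values[valid] / t2w@values[valid]
  new("RatioMaps", t1t2 = out,
      st1t2 = array(numeric(0), c(0L, 0L, 0L)),
      scalingFactor = numeric(0), validMask = valid,
      voxelSizeMM = t1w@voxelSizeMM)
}

#' Compute the standardized sT1w/T2w ratio map
#'
#' With `sT2 = scalingFactor * T2w`, computes voxelwise
#' `(T1w - sT2) / (T1w + sT2)` inside the brain. Voxels where the
#' denominator `T1w + sT2` is at or below `eps` are excluded. Wherever both
#' inputs are strictly positive the value lies strictly inside (-1, 1):
#' gray matter maps near 0, white matter to (0, 1), CSF to (-1, 0). The map
#' is invariant to independent global gains on T1w and T2w once the scaling
#' factor is recomputed, which is the mechanism by which standardization
#' removes between-subject scanner-scale variability.
#'
#' @param t1w,t2w [ImageVolume-class] objects on one grid.
#' @param scalingFactor positive scalar from [computeScalingFactor()].
#' @param brain logical brain mask.
#' @param eps denominator guard; default `1e-6 *` median brain (T1w + sT2).
#' @return a [RatioMaps-class] with the `st1t2` map, `scalingFactor` and
#'   `validMask` set.
#' @export
computeST1T2Ratio <- function(t1w, t2w, scalingFactor, brain, eps = NULL) {
  stopifnot(identical(dim(t1w@values), dim(t2w@values)),
            identical(dim(t1w@values), dim(brain)))
  if (scalingFactor <= 0)
    stop("contract violation: scaling factor must be > 0")
  st2 <- scalingFactor * t2w@values
  den <- t1w@values + st2
  if (is.null(eps)) eps <- defaultEps(den, brain)
  valid <- brain & den > eps
  out <- array(NA_real_, dim(t1w@values))
  out[valid] <- (t1w@values[valid] - st2[valid]) / den[valid]
  new("RatioMaps", t1t2 = array(numeric(0), c(0L, 0L, 0L)), st1t2 = out,
      scalingFactor = scalingFactor, validMask = valid,
      voxelSizeMM = t1w@voxelSizeMM)
}

#' Compute both ratio maps for one subject
#'
#' Convenience wrapper: derives the NAGM scaling factor, the classic ratio
#' and the standardized ratio, combined into a single [RatioMaps-class]
#' whose valid mask is the intersection of the two per-map guards.
#'
#' @inheritParams computeT1T2Ratio
#' @param masks a [TissueMaskSet-class] with NAGM populated
#'   (see [makeNAMasks()]).
#' @return a [RatioMaps-class] with both maps populated.
#' @export
computeRatioMaps <- function(t1w, t2w, masks, eps = NULL) {
  if (!length(masks@nagm)) masks <- makeNAMasks(masks)
  sf <- computeScalingFactor(t1w, t2w, masks@nagm)
  r1 <- computeT1T2Ratio(t1w, t2w, masks@brain, eps)
  r2 <- computeST1T2Ratio(t1w, t2w, sf, masks@brain, eps)
  new("RatioMaps", t1t2 = r1@t1t2, st1t2 = r2@st1t2, scalingFactor = sf,
      validMask = r1@validMask & r2@validMask, voxelSizeMM = t1w@voxelSizeMM)
}

#' Extract per-tissue median intensities
#'
#' Median T1w, T2w, T1w/T2w and standardized-ratio values over the NAGM,
#' NAWM and CSF regions of one subject. Ratio medians are taken over the
#' region intersected with the maps' valid mask. Medians over an even
#' number of voxels use the midpoint of the two central order statistics.
#'
#' @param t1w,t2w (bias-corrected) [ImageVolume-class] objects.
#' @param maps a [RatioMaps-class] with both maps populated.
#' @param masks a [TissueMaskSet-class] with NAGM/NAWM populated.
#' @param subjectId subject identifier recorded in the output.
#' @return a long `data.frame` with columns `subject_id`, `measure`
#'   (`T1w`, `T2w`, `t1t2`, `st1t2`), `region` (`NAGM`, `NAWM`, `CSF`) and
#'   `median`; NaN-free.
#' @export
extractTissueMedians <- function(t1w, t2w, maps, masks, subjectId) {
  if (!length(masks@nagm)) masks <- makeNAMasks(masks)
  regions <- list(NAGM = masks@nagm, NAWM = masks@nawm, CSF = masks@csf)
  sources <- list(T1w = list(v = t1w@values, guard = FALSE),
                  T2w = list(v = t2w@values, guard = FALSE),
                  t1t2 = list(v = maps@t1t2, guard = TRUE),
                  st1t2 = list(v = maps@st1t2, guard = TRUE))
  rows <- expand.grid(measure = names(sources), region = names(regions),
                      stringsAsFactors = FALSE)
  rows$median <- mapply(function(ms, rg) {
    sel <- regions[[rg]]
    if (sources[[ms]]$guard) sel <- sel & maps@validMask
    if (!any(sel))
      stop(sprintf("degenerate region: %s has no valid voxels for %s", rg, ms))
    median(sources[[ms]]$v[sel])
  }, rows$measure, rows$region)
  if (any(!is.finite(rows$median)))
    stop("non-finite tissue median")
  data.frame(subject_id = subjectId, rows, stringsAsFactors = FALSE)
}
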