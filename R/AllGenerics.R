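#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageVolume-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname RatioMaps-class
#' @export
setGeneric("scalingFactor", function(x) standardGeneric("scalingFactor"))

#' @rdname RatioMaps-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname StepwiseFit-class
#' @export
setGeneric("selectedModel", function(x) standardGeneric("selectedModel"))

#' @rdname StepwiseFit-class
#' @export
setGeneric("modelPath", function(x) standardGeneric("modelPath"))

#' @rdname CohortReport-class
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @rdname CohortReport-class
#' @export
setGeneric("tissueMedians", function(x) standardGeneric("tissueMedians"))

#' @rdname ImageVolume-class
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)

#' @rdname ImageVolume-class
#' @export
setMethod("voxelSize", "ImageVolume", function(x) x@voxelSizeMM)

#' @rdname ImageVolume-class
#' @export
setMethod("modality", "ImageVolume", function(x) x@modality)

#' @rdname RatioMaps-class
#' @export
setMethod("scalingFactor", "RatioMaps", function(x) x@scalingFactor)

#' @rdname RatioMaps-class
#' @export
setMethod("validMask", "RatioMaps", function(x) x@validMask)

#' @rdname StepwiseFit-class
#' @export
setMethod("selectedModel", "StepwiseFit", function(x) x@path[[x@selected]])

#' @rdname StepwiseFit-class
#' @export
setMethod("modelPath", "StepwiseFit", function(x) x@path)

#' @rdname CohortReport-class
#' @export
setMethod("subjectTable", "CohortReport", function(x) x@subjects)

#' @rdname CohortReport-class
#' @export
setMethod("tissueMedians", "CohortReport", function(x) x@medians)

#' @rdname ImageVolume-class
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@values))

#' @rdname TissueMaskSet-class
#' @export
setMethod("dim", "TissueMaskSet", function(x) dim(x@brain))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume [%s]: %d x %d x %d voxels @ %.3g mm, range [%.4g, %.4g]\n",
              object@modality, d[1], d[2], d[3], object@voxelSizeMM,
              min(object@values), max(object@values)))
})

setMethod("show", "TissueMaskSet", function(object) {
  d <- dim(object@brain)
  cnt <- function(m) if (length(m)) sum(m) else NA_integer_
  cat(sprintf("TissueMaskSet on %d x %d x %d grid\n", d[1], d[2], d[3]))
  cat(sprintf("  brain %d | csf %d | gm %d | wm %d | lesion %d\n",
              cnt(object@brain), cnt(object@csf), cnt(object@gm),
              cnt(object@wm), cnt(object@lesion)))
  if (length(object@nagm))
    cat(sprintf("  nagm %d | nawm %d\n", cnt(object@nagm), cnt(object@nawm)))
  else cat("  normal-appearing masks not yet derived (see makeNAMasks)\n")
})

setMethod("show", "RatioMaps", function(object) {
  cat("RatioMaps\n")
  if (length(object@scalingFactor))
    cat(sprintf("  scaling factor: %.4f\n", object@scalingFactor))
  if (length(object@validMask))
    cat(sprintf("  valid voxels: %d\n", sum(object@validMask)))
  for (s in c("t1t2", "st1t2")) {
    v <- slot(object, s)
    if (length(v)) {
      ok <- v[object@validMask]
      cat(sprintf("  %s: median %.4f over valid voxels\n", s, median(ok)))
    }
  }
})

setMethod("show", "StepwiseFit", function(object) {
  cat(sprintf("StepwiseFit for '%s': %d model(s), removal threshold p < %.3g\n",
              object@response, length(object@path), object@threshold))
  for (i in seq_along(object@path)) {
    m <- object@path[[i]]
    sel <- if (i == object@selected) " <- selected (min AIC)" else ""
    cat(sprintf("  [%d] ~ %s | n=%d adjR2=%.3f AIC=%.2f maxCook=%.3f%s\n",
                i, if (length(m$terms)) paste(m$terms, collapse = " + ") else "1",
                m$n, m$adj_r2, m$aic, m$max_cooks, sel))
  }
})

setMethod("show", "CohortReport", function(object) {
  n <- table(object@subjects$group)
  cat(sprintf("CohortReport: %d MS / %d HC subjects\n", n[["MS"]], n[["HC"]]))
  cat("NAWM coefficient of variation (%):\n")
  print(object@covTable, row.names = FALSE)
  for (g in names(object@covTests)) {
    ct <- object@covTests[[g]]
    cat(sprintf("  CoV equality (%s): chi-sq = %.2f, df = %d, p = %.3g\n",
                g, ct$statistic, ct$df, ct$p_value))
  }
  sig <- object@groupComparisons[object@groupComparisons$significant, ]
  cat(sprintf("Group differences passing Bonferroni gate (p < %.3g): %s\n",
              object@settings$alpha,
              if (nrow(sig)) paste(sig$measure, sig$region, collapse = ", ")
              else "none"))
})
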