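## Bias-field estimation/correction and lesion-aware mask arithmetic.

#' Estimate a smooth multiplicative bias field
#'
#' Models the log bias field inside the brain as a 3D polynomial of the
#' given total degree and estimates its coefficients in the gradient
#' domain: for every pair of adjacent brain voxels, the difference of log
#' intensities equals the difference of the log field wherever both voxels
#' belong to the same tissue, while pairs straddling a tissue boundary are
#' sparse gross outliers. A trimmed least-squares fit of the polynomial
#' basis differences to the observed log-intensity differences (iterated
#' until the retained set stabilises, then refined on all pairs within 2.5
#' robust SDs) therefore recovers the field without absorbing anatomical
#' contrast into the polynomial, the failure mode of a naive whole-brain
#' intensity fit. The returned field is the exponentiated polynomial,
#' rescaled so its mean over the brain is exactly 1 (the gradient fit
#' leaves the constant term free; normalisation pins it down).
#' Non-positive voxels inside the brain are excluded from the fit (with a
#' message), never clamped.
#'
#' @param volume an [ImageVolume-class], strictly positive inside `brain`.
#' @param brain logical 3D brain mask.
#' @param degree polynomial total degree, 1, 2 or 3 (default 2).
#' @param trim fraction of voxel pairs retained in each trimmed refit;
#'   1 - trim must exceed the fraction of tissue-boundary pairs.
#' @param maxIter iteration cap for the trimmed refits.
#' @return an [ImageVolume-class] with modality `"field"`, positive
#'   everywhere, mean 1 over the brain.
#' @export
estimateBiasField <- function(volume, brain, degree = 2L, trim = 0.8,
                              maxIter = 30L) {
  stopifnot(degree %in% 1:3, trim > 0, trim <= 1)
  dims <- dim(volume@values)
  stopifnot(identical(dims, dim(brain)))
  usable <- brain & volume@values > 0
  nbad <- sum(brain) - sum(usable)
  if (nbad > 0)
    message(sprintf("bias fit: excluding %d non-positive voxel(s) inside brain",
                    nbad))
  Bfull <- fullGridBasis(dims, degree)[, -1, drop = FALSE]  # intercept via normalisation
  logV <- array(NA_real_, dims)
  logV[usable] <- log(volume@values[usable])

  # adjacent same-usable voxel pairs along each axis
  n <- prod(dims)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  idx <- which(usable)
  ylist <- list(); xlist <- list()
  for (a in 1:3) {
    lower <- idx[arrayInd(idx, dims)[, a] < dims[a]]
    upper <- lower + strides[a]
    ok <- usable[upper]
    lower <- lower[ok]; upper <- upper[ok]
    ylist[[a]] <- logV[upper] - logV[lower]
    xlist[[a]] <- Bfull[upper, , drop = FALSE] - Bfull[lower, , drop = FALSE]
  }
  y <- unlist(ylist)
  X <- do.call(rbind, xlist)
  if (length(y) < ncol(X))
    stop(sprintf("underdetermined bias fit: %d voxel pairs for %d basis terms",
                 length(y), ncol(X)))
  if (length(y) > 50000L) {
    # deterministic stride subsample: the fit is heavily overdetermined
    pick <- unique(as.integer(seq(1L, length(y), length.out = 50000L)))
    y <- y[pick]
    X <- X[pick, , drop = FALSE]
  }
  beta <- .lm.fit(X, y)$coefficients
  h <- max(ceiling(trim * length(y)), ncol(X) + 1L)
  rssPrev <- Inf
  for (it in seq_len(maxIter)) {
    res2 <- (y - as.vector(X %*% beta))^2
    sel <- order(res2)[seq_len(h)]
    rss <- sum(res2[sel])
    if (rss >= rssPrev * (1 - 1e-12)) break  # C-steps are monotone
    rssPrev <- rss
    beta <- .lm.fit(X[sel, , drop = FALSE], y[sel])$coefficients
  }
  res <- y - as.vector(X %*% beta)
  keep <- abs(res - median(res)) < 2.5 * (stats::mad(res) + 1e-12)
  if (sum(keep) > ncol(X))
    beta <- .lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
  field <- array(exp(as.vector(Bfull %*% beta)), dims)
  field <- field / mean(field[brain])
  imageVolume(field, volume@voxelSizeMM, "field")
}

#' Divide out a bias field inside the brain
#'
#' Voxels inside the brain are divided by the field; voxels outside pass
#' through unchanged.
#'
#' @param volume an [ImageVolume-class].
#' @param field an [ImageVolume-class] with modality `"field"`, strictly
#'   positive inside `brain`.
#' @param brain logical 3D brain mask.
#' @return a bias-corrected [ImageVolume-class].
#' @export
correctBias <- function(volume, field, brain) {
  stopifnot(identical(dim(volume@values), dim(field@values)),
            identical(dim(volume@values), dim(brain)))
  if (any(field@values[brain] <= 0))
    stop("invalid field: non-positive value inside brain")
  out <- volume@values
  out[brain] <- out[brain] / field@values[brain]
  imageVolume(out, volume@voxelSizeMM, volume@modality)
}

#' Derive normal-appearing tissue masks
#'
#' Populates NAGM = GM AND NOT lesion and NAWM = WM AND NOT lesion, the
#' lesion-subtraction step that defines the normal-appearing regions used
#' by every downstream statistic. Idempotent.
#'
#' @param masks a [TissueMaskSet-class] with valid base masks.
#' @param verbose emit voxel counts as a message.
#' @return the same mask set with `nagm`/`nawm` populated.
#' @export
makeNAMasks <- function(masks, verbose = FALSE) {
  validObject(masks)
  nagm <- masks@gm & !masks@lesion
  nawm <- masks@wm & !masks@lesion
  if (!any(nawm) || !any(nagm))
    stop("degenerate segmentation: empty normal-appearing mask after lesion subtraction")
  if (verbose)
    message(sprintf("na-masks: nagm %d voxels (gm %d), nawm %d voxels (wm %d), lesion %d",
                    sum(nagm), sum(masks@gm), sum(nawm), sum(masks@wm),
                    sum(masks@lesion)))
  masks@nagm <- nagm
  masks@nawm <- nawm
  validObject(masks)
  masks
}
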