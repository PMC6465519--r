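## NIfTI-1 I/O (via RNifti) and integer-label <-> mask conversion.

LABEL_CODES <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L, lesion = 4L)

writeNiftiArray <- function(values, voxelSizeMM, file) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(voxelSizeMM, 3L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read and write ImageVolume objects as NIfTI-1
#'
#' @param x an [ImageVolume-class].
#' @param file path to a `.nii` / `.nii.gz` file.
#' @param modality modality tag to attach on read.
#' @return `readNiftiVolume` returns an [ImageVolume-class];
#'   `writeNiftiVolume` returns the file path invisibly.
#' @export
writeNiftiVolume <- function(x, file) {
  writeNiftiArray(x@values, x@voxelSizeMM, file)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(file, modality) {
  img <- RNifti::readNifti(file)
  vox <- RNifti::pixdim(img)[1]
  imageVolume(array(as.numeric(img), dim = dim(img)), vox, modality)
}

#' Convert between an integer label volume and tissue masks
#'
#' The label code table is 0 background, 1 CSF, 2 GM, 3 WM, 4 lesion.
#' Lesions arise inside white matter, so the WM mask is the union of codes
#' 3 and 4 and NAWM (WM with lesions subtracted) is exactly code 3.
#'
#' @param labels 3D integer array of label codes.
#' @param masks a [TissueMaskSet-class].
#' @return `labelsToMasks` returns a [TissueMaskSet-class];
#'   `masksToLabels` returns an integer array.
#' @export
labelsToMasks <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), LABEL_CODES)
  if (length(bad))
    stop("unknown label codes: ", paste(bad, collapse = ", "))
  tissueMaskSet(
    brain = labels != LABEL_CODES[["background"]],
    csf = labels == LABEL_CODES[["csf"]],
    gm = labels == LABEL_CODES[["gm"]],
    wm = labels == LABEL_CODES[["wm"]] | labels == LABEL_CODES[["lesion"]],
    lesion = labels == LABEL_CODES[["lesion"]]
  )
}

#' @rdname labelsToMasks
#' @export
masksToLabels <- function(masks) {
  labels <- array(LABEL_CODES[["background"]], dim(masks@brain))
  labels[masks@csf] <- LABEL_CODES[["csf"]]
  labels[masks@gm] <- LABEL_CODES[["gm"]]
  labels[masks@wm] <- LABEL_CODES[["wm"]]
  labels[masks@lesion] <- LABEL_CODES[["lesion"]]
  labels
}
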