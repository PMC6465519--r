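## Synthetic two-group MRI cohort: subject table, label phantoms,
## intensity rendering.

drawLesionCounts <- function(n, mean, sd) {
  if (mean <= 0) return(integer(n))
  v <- sd^2
  if (v > mean) {
    # moment-matched negative binomial (counts are overdispersed)
    size <- mean^2 / (v - mean)
    rnbinom(n, size = size, mu = mean)
  } else {
    rpois(n, mean)
  }
}

drawLesionVolumes <- function(counts, mean, sd, cap) {
  out <- numeric(length(counts))
  pos <- counts > 0L
  if (any(pos)) {
    if (mean <= 0) {
      # positive count but a zero-volume target is contradictory; give each
      # lesion one nominal-ml-scale minimum handled at rasterisation
      out[pos] <- 0
    } else {
      p <- lognormalMoments(mean, sd)
      out[pos] <- pmin(rlnorm(sum(pos), p["meanlog"], p["sdlog"]), cap)
    }
  }
  out
}

#' Generate the cohort subject table
#'
#' Draws `2 * nPerGroup` subjects: MS patients with ages from a truncated
#' normal and a matched healthy control (HC) partner of identical sex and
#' age within +/- 0.5 years. Lesion counts come from a moment-matched
#' negative binomial (Poisson fallback when variance <= mean), lesion
#' volumes from a moment-matched lognormal (zero iff the count is zero),
#' EDSS from a truncated normal rounded to the 0.5 grid (patients only),
#' disease duration from a moment-matched lognormal, and head-size scaling
#' factors from sex-specific normals. Deterministic given the config seed.
#'
#' @param config a [GeneratorConfig-class].
#' @return a `data.frame` with columns `subject_id`, `group`, `age`, `sex`,
#'   `head_size_scale`, `edss`, `disease_duration_months`,
#'   `lesion_volume_ml`, `lesion_count`. MS and HC rows are pair-aligned
#'   (row i of each group forms a matched pair).
#' @examples
#' tab <- generateSubjectTable(generatorConfig(nPerGroup = 5L, seed = 7L))
#' @export
generateSubjectTable <- function(config) {
  validObject(config)
  n <- config@nPerGroup
  withSeed(deriveSeed(config@seed, "subjects"), {
    sex <- rep(c("F", "M"), c(config@femaleCount, n - config@femaleCount))
    ageMS <- rtruncnorm(n, config@ageMean, config@ageSd,
                        config@ageRange[1], config@ageRange[2])
    ageHC <- pmin(pmax(ageMS + runif(n, -0.5, 0.5),
                       config@ageRange[1]), config@ageRange[2])
    cntMS <- drawLesionCounts(n, config@lesionCountMoments["ms", "mean"],
                              config@lesionCountMoments["ms", "sd"])
    cntHC <- drawLesionCounts(n, config@lesionCountMoments["hc", "mean"],
                              config@lesionCountMoments["hc", "sd"])
    volMS <- drawLesionVolumes(cntMS, config@lesionVolumeMoments["ms", "mean"],
                               config@lesionVolumeMoments["ms", "sd"],
                               config@lesionVolumeMax)
    volHC <- drawLesionVolumes(cntHC, config@lesionVolumeMoments["hc", "mean"],
                               config@lesionVolumeMoments["hc", "sd"],
                               config@lesionVolumeMax)
    edss <- rtruncnorm(n, config@edssMean, config@edssSd,
                       config@edssRange[1], config@edssRange[2])
    edss <- pmin(pmax(round(edss * 2) / 2, config@edssRange[1]),
                 config@edssRange[2])
    dm <- config@durationMoments
    dp <- lognormalMoments(dm[["mean"]], dm[["sd"]])
    duration <- rlnorm(n, dp["meanlog"], dp["sdlog"])
    hsMean <- ifelse(sex == "F", config@headSizeMeanF, config@headSizeMeanM)
    hs <- c(rnorm(n, hsMean, config@headSizeSd),
            rnorm(n, hsMean, config@headSizeSd))
    tab <- data.frame(
      subject_id = c(sprintf("MS%03d", seq_len(n)), sprintf("HC%03d", seq_len(n))),
      group = rep(c("MS", "HC"), each = n),
      age = c(ageMS, ageHC),
      sex = rep(sex, 2L),
      head_size_scale = hs,
      edss = c(edss, rep(NA_real_, n)),
      disease_duration_months = c(duration, rep(NA_real_, n)),
      lesion_volume_ml = c(volMS, volHC),
      lesion_count = as.integer(c(cntMS, cntHC)),
      stringsAsFactors = FALSE
    )
    if (config@missingHeadSize)
      tab$head_size_scale[sample(nrow(tab), 1L)] <- NA_real_
    tab
  })
}

# Ellipsoid radii as fractions of the half-extent of the grid; the
# head-size scaling factor (a standard-space normalisation analog, larger
# = smaller head) modulates them as scale^(-1/3).
phantomRadii <- function(config, headSize) {
  ref <- (config@headSizeMeanF + config@headSizeMeanM) / 2
  if (is.na(headSize)) headSize <- ref
  c(0.84, 0.76, 0.68) * (ref / headSize)^(1 / 3)
}

#' Generate the tissue label phantom for one subject
#'
#' Builds a geometric brain phantom on the configured grid: an ellipsoidal
#' brain containing a central CSF core, a white-matter interior and a
#' gray-matter shell, with the subject's lesions rasterised as compact
#' blobs inside deep white matter whose total voxel volume matches the
#' subject's T2 lesion volume (exact up to voxel rounding). The subject's
#' head-size scaling factor modulates the ellipsoid radii. Deterministic
#' given config seed and subject id.
#'
#' @param record one row of the subject table ([generateSubjectTable()]).
#' @param config a [GeneratorConfig-class].
#' @return a [TissueMaskSet-class]; WM includes lesion voxels, so NAWM
#'   (after [makeNAMasks()]) is WM with lesions subtracted.
#' @export
generateLabelVolume <- function(record, config) {
  validObject(config)
  dims <- config@gridShape
  co <- gridCoords(dims)
  rad <- phantomRadii(config, record$head_size_scale)
  r <- sqrt((co$x / rad[1])^2 + (co$y / rad[2])^2 + (co$z / rad[3])^2)
  brain <- r <= 1
  csf <- r <= 0.30
  wm <- r > 0.30 & r <= 0.82
  gm <- r > 0.82 & brain

  lesion <- array(FALSE, dims)
  count <- record$lesion_count
  if (count > 0L) {
    voxvol <- config@voxelSizeMM^3                      # mm^3
    nTarget <- max(round(record$lesion_volume_ml * 1000 / voxvol), count)
    if (nTarget > 0.5 * sum(wm))
      stop(sprintf("infeasible phantom for %s: lesion volume %.1f ml exceeds available white matter",
                   record$subject_id, record$lesion_volume_ml))
    sizes <- rep(nTarget %/% count, count)
    extra <- nTarget - sum(sizes)
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    withSeed(deriveSeed(config@seed, "labels", record$subject_id), {
      deep <- which(wm & r >= 0.35 & r <= 0.75)
      centers <- sample(deep, count, replace = count > length(deep))
      cidx <- arrayInd(centers, dims)
      for (i in seq_len(count)) {
        k <- sizes[i]
        wHalf <- ceiling((3 * k / (4 * pi))^(1 / 3)) + 2L
        repeat {
          xs <- max(1L, cidx[i, 1] - wHalf):min(dims[1], cidx[i, 1] + wHalf)
          ys <- max(1L, cidx[i, 2] - wHalf):min(dims[2], cidx[i, 2] + wHalf)
          zs <- max(1L, cidx[i, 3] - wHalf):min(dims[3], cidx[i, 3] + wHalf)
          sub <- expand.grid(x = xs, y = ys, z = zs)
          lin <- sub$x + (sub$y - 1L) * dims[1] + (sub$z - 1L) * dims[1] * dims[2]
          free <- wm[lin] & !lesion[lin]
          if (sum(free) >= k ||
              (length(xs) == dims[1] && length(ys) == dims[2] && length(zs) == dims[3]))
            break
          wHalf <- wHalf * 2L
        }
        lin <- lin[free]
        sub <- sub[free, , drop = FALSE]
        d2 <- (sub$x - cidx[i, 1])^2 + (sub$y - cidx[i, 2])^2 + (sub$z - cidx[i, 3])^2
        take <- lin[order(d2)][seq_len(min(k, length(lin)))]
        lesion[take] <- TRUE
      }
    })
  }
  tissueMaskSet(brain = brain, gm = gm, wm = wm, csf = csf, lesion = lesion)
}

# Smooth multiplicative bias field: exponentiated random degree-2
# polynomial, centred over the brain, scaled so the maximal fractional
# deviation inside the brain is `amplitude`, then normalised to brain mean 1.
makeBiasField <- function(dims, brain, amplitude) {
  B <- fullGridBasis(dims, 2L)
  p <- as.vector(B[, -1, drop = FALSE] %*% rnorm(ncol(B) - 1L))
  p <- p - mean(p[brain])
  mx <- max(abs(p[brain]))
  if (mx > 0) p <- p * log1p(amplitude) / mx
  f <- array(exp(p), dims)
  f / mean(f[brain])
}

#' Render T1w and T2w intensity volumes for one subject
#'
#' Paints each tissue with its configured mean intensity, implants the
#' subject's target NAWM standardized-ratio median
#' `s* = baseline + effectMS * [group == MS] + effectAge * (age - ageMean)
#' + effectLesionCount * count` by setting the WM T1w mean to
#' `w * (1 + s*) / (1 - s*)` where `w` is the noise-free scaled-T2w WM
#' value, gives lesion voxels distinct T2w-hyperintense / T1w-hypointense
#' means, then applies the per-subject multiplicative lognormal gain and a
#' smooth multiplicative bias field per modality and adds Gaussian noise.
#' All values are clipped to be strictly positive. Deterministic given
#' config seed and subject id.
#'
#' @param masks the subject's [TissueMaskSet-class].
#' @param record one subject-table row.
#' @param config a [GeneratorConfig-class].
#' @return a list with elements `t1w`, `t2w` ([ImageVolume-class]),
#'   `biasT1w`, `biasT2w` (the generating fields, modality `"field"`),
#'   `gains` (named numeric) and `sTarget` (the implanted median).
#' @export
renderIntensityVolumes <- function(masks, record, config) {
  m1 <- config@tissueMeansT1w
  m2 <- config@tissueMeansT2w
  s <- config@stBaseline +
    config@effectMS * (record$group == "MS") +
    config@effectAge * (record$age - config@ageMean) +
    config@effectLesionCount * record$lesion_count
  if (abs(s) >= 1)
    stop(sprintf("invalid effect configuration: implanted standardized-ratio median %.3f outside (-1, 1)", s))
  # noise-free scaled-T2w WM value; the NAGM scaling factor is gm T1w/T2w
  w <- (m1[["gm"]] / m2[["gm"]]) * m2[["wm"]]
  wmT1 <- w * (1 + s) / (1 - s)

  dims <- config@gridShape
  nawm <- masks@wm & !masks@lesion
  nagm <- masks@gm & !masks@lesion
  t1 <- array(1.0, dims)
  t2 <- array(1.0, dims)
  t1[masks@csf] <- m1[["csf"]]; t2[masks@csf] <- m2[["csf"]]
  t1[nagm] <- m1[["gm"]];       t2[nagm] <- m2[["gm"]]
  t1[nawm] <- wmT1;             t2[nawm] <- m2[["wm"]]
  t1[masks@lesion] <- m1[["lesion"]]; t2[masks@lesion] <- m2[["lesion"]]

  withSeed(deriveSeed(config@seed, "render", record$subject_id), {
    if (config@biasAmplitude > 0) {
      f1 <- makeBiasField(dims, masks@brain, config@biasAmplitude)
      f2 <- makeBiasField(dims, masks@brain, config@biasAmplitude)
    } else {
      f1 <- f2 <- array(1.0, dims)
    }
    g1 <- exp(rnorm(1L, 0, config@gainSdT1w))
    g2 <- exp(rnorm(1L, 0, config@gainSdT2w))
    t1 <- t1 * g1 * f1
    t2 <- t2 * g2 * f2
    if (config@noiseSd > 0) {
      t1 <- t1 + rnorm(length(t1), 0, config@noiseSd)
      t2 <- t2 + rnorm(length(t2), 0, config@noiseSd)
    }
  })
  t1 <- pmax(t1, 1e-6)
  t2 <- pmax(t2, 1e-6)
  list(
    t1w = imageVolume(array(t1, dims), config@voxelSizeMM, "T1w"),
    t2w = imageVolume(array(t2, dims), config@voxelSizeMM, "T2w"),
    biasT1w = imageVolume(f1, config@voxelSizeMM, "field"),
    biasT2w = imageVolume(f2, config@voxelSizeMM, "field"),
    gains = c(t1w = g1, t2w = g2),
    sTarget = unname(s)
  )
}

#' Write a full synthetic cohort to disk
#'
#' Generates the subject table and, for every subject, the label phantom
#' and both intensity volumes, written as NIfTI-1 (`<id>_T1w.nii.gz`,
#' `<id>_T2w.nii.gz`, and `<id>_labels.nii.gz` with integer codes
#' 0 background, 1 CSF, 2 GM, 3 WM, 4 lesion) plus `subjects.tsv`.
#'
#' @param config a [GeneratorConfig-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the subject table.
#' @export
simulateCohort <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- generateSubjectTable(config)
  utils::write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(tab))) {
    rec <- tab[i, ]
    masks <- generateLabelVolume(rec, config)
    labels <- masksToLabels(masks)
    ren <- renderIntensityVolumes(masks, rec, config)
    writeNiftiVolume(ren$t1w, file.path(dir, paste0(rec$subject_id, "_T1w.nii.gz")))
    writeNiftiVolume(ren$t2w, file.path(dir, paste0(rec$subject_id, "_T2w.nii.gz")))
    writeNiftiArray(labels, config@voxelSizeMM,
                    file.path(dir, paste0(rec$subject_id, "_labels.nii.gz")))
  }
  invisible(tab)
}
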