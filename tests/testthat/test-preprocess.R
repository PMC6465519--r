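phantomWithBias <- function(seed = 41L, amplitude = 0.2, noiseSd = 0) {
  cfg <- testConfig(nPerGroup = 2L, femaleCount = 1L, noiseSd = noiseSd,
                    gainSdT1w = 0, gainSdT2w = 0, biasAmplitude = amplitude,
                    seed = seed)
  rec <- firstSubject(cfg)
  masks <- makeNAMasks(generateLabelVolume(rec, cfg))
  list(cfg = cfg, rec = rec, masks = masks,
       ren = renderIntensityVolumes(masks, rec, cfg))
}

test_that("bias field of a constant volume is one and mean-normalised", {
  dims <- c(20L, 20L, 20L)
  brain <- array(FALSE, dims)
  brain[5:16, 5:16, 5:16] <- TRUE
  vol <- imageVolume(array(7.5, dims), 1, "T1w")
  f <- estimateBiasField(vol, brain)
  expect_lt(max(abs(voxelData(f)[brain] - 1)), 1e-10)
  expect_lt(abs(mean(voxelData(f)[brain]) - 1), 1e-10)
})

test_that("a known smooth field is recovered within 2% RMS inside brain", {
  p <- phantomWithBias(seed = 43L)
  for (m in c("t1w", "t2w")) {
    truth <- if (m == "t1w") p$ren$biasT1w else p$ren$biasT2w
    est <- estimateBiasField(p$ren[[m]], p$masks@brain)
    rel <- voxelData(est)[p$masks@brain] / voxelData(truth)[p$masks@brain]
    expect_lt(sqrt(mean((rel - 1)^2)), 0.02)
    expect_lt(abs(mean(voxelData(est)[p$masks@brain]) - 1), 1e-10)
    expect_true(all(voxelData(est) > 0))
  }
})

test_that("bias fit excludes non-positive voxels and flags them", {
  p <- phantomWithBias(seed = 47L)
  vol <- p$ren$t1w
  v <- voxelData(vol)
  idx <- which(p$masks@brain)[1:5]
  v[idx] <- 0
  # bypass the raw-modality positivity validity on purpose: a ratio-tagged
  # volume may carry zeros
  broken <- imageVolume(v, voxelSize(vol), "ratio")
  expect_message(estimateBiasField(broken, p$masks@brain), "non-positive")
})

test_that("underdetermined bias fits are rejected", {
  dims <- c(16L, 16L, 16L)
  brain <- array(FALSE, dims)
  brain[8, 8, 8:9] <- TRUE  # two voxels: one pair
  vol <- imageVolume(array(5, dims), 1, "T1w")
  expect_error(estimateBiasField(vol, brain), "underdetermined")
})

test_that("correctBias divides inside brain and passes outside through", {
  p <- phantomWithBias(seed = 53L)
  vol <- p$ren$t1w
  brain <- p$masks@brain
  one <- imageVolume(array(1, dim(vol)), voxelSize(vol), "field")
  expect_identical(voxelData(correctBias(vol, one, brain)), voxelData(vol))
  # inverse property: correcting v*f by f restores v
  f <- p$ren$biasT1w
  v <- voxelData(vol) / voxelData(f)  # the unbiased image
  biased <- imageVolume(v * voxelData(f), voxelSize(vol), "T1w")
  got <- correctBias(biased, f, brain)
  expect_equal(voxelData(got)[brain], v[brain], tolerance = 1e-12)
  # outside brain untouched even for a wild field
  wild <- imageVolume(array(0.1, dim(vol)), voxelSize(vol), "field")
  expect_identical(voxelData(correctBias(vol, wild, brain))[!brain],
                   voxelData(vol)[!brain])
  bad <- imageVolume(array(-1, dim(vol)), voxelSize(vol), "field")
  expect_error(correctBias(vol, bad, brain), "invalid field")
})

test_that("correction lowers within-tissue dispersion on a biased phantom", {
  p <- phantomWithBias(seed = 59L, noiseSd = 2)
  wm <- p$masks@nawm
  covOf <- function(vol) sd(voxelData(vol)[wm]) / mean(voxelData(vol)[wm])
  est <- estimateBiasField(p$ren$t1w, p$masks@brain)
  corrected <- correctBias(p$ren$t1w, est, p$masks@brain)
  expect_lt(covOf(corrected), covOf(p$ren$t1w))
})

test_that("bias correction commutes with global rescaling", {
  p <- phantomWithBias(seed = 61L)
  vol <- p$ren$t1w
  brain <- p$masks@brain
  scaled <- imageVolume(3.7 * voxelData(vol), voxelSize(vol), "T1w")
  c1 <- correctBias(vol, estimateBiasField(vol, brain), brain)
  c2 <- correctBias(scaled, estimateBiasField(scaled, brain), brain)
  ratio <- voxelData(c2)[brain] / voxelData(c1)[brain]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
})

test_that("normal-appearing mask arithmetic subtracts lesions from both tissues", {
  cfg <- testConfig(seed = 67L)
  rec <- firstSubject(cfg)
  masks <- generateLabelVolume(rec, cfg)
  na1 <- makeNAMasks(masks)
  k <- sum(masks@lesion & masks@wm)
  expect_gt(k, 0L)
  expect_equal(sum(na1@nawm), sum(masks@wm) - k)
  expect_identical(na1@nagm, masks@gm & !masks@lesion)
  # idempotent
  expect_identical(makeNAMasks(na1)@nawm, na1@nawm)

  # toy straddle: a lesion across the GM/WM border leaves both NA masks
  dims <- c(16L, 16L, 16L)
  mk <- function(ix) { a <- array(FALSE, dims); a[ix] <- TRUE; a }
  brain <- array(TRUE, dims)
  gm <- mk(1:100); wm <- mk(101:200); csf <- mk(201:250)
  lesion <- mk(99:102)  # two GM voxels, two WM voxels
  toy <- makeNAMasks(tissueMaskSet(brain, gm, wm, csf, lesion))
  expect_equal(sum(toy@nagm), 98L)
  expect_equal(sum(toy@nawm), 98L)
  expect_false(any(toy@nagm & lesion) || any(toy@nawm & lesion))

  # fully lesioned WM is degenerate
  expect_error(makeNAMasks(tissueMaskSet(brain, gm, wm, csf, wm)),
               "degenerate")
})
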