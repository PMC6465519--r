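constVol <- function(value, dims = c(12L, 12L, 12L), modality = "T1w") {
  imageVolume(array(value, dims), 1, modality)
}

test_that("scaling factor is the ratio of NAGM medians", {
  dims <- c(12L, 12L, 12L)
  nagm <- array(FALSE, dims); nagm[4:9, 4:9, 4:9] <- TRUE
  expect_equal(computeScalingFactor(constVol(300), constVol(60, modality = "T2w"),
                                    nagm), 5.0)
  # homogeneity: scaling T2w by b divides the factor by b
  expect_equal(computeScalingFactor(constVol(300), constVol(60 * 2.5, modality = "T2w"),
                                    nagm), 5.0 / 2.5)
  expect_error(computeScalingFactor(constVol(300), constVol(0, modality = "T2w"),
                                    nagm), "corrupt")
})

test_that("noise-free phantom scaling factor equals the configured GM ratio", {
  cfg <- cleanConfig(seed = 71L)
  rec <- firstSubject(cfg)
  masks <- makeNAMasks(generateLabelVolume(rec, cfg))
  ren <- renderIntensityVolumes(masks, rec, cfg)
  sf <- computeScalingFactor(ren$t1w, ren$t2w, masks@nagm)
  expect_equal(sf, cfg@tissueMeansT1w[["gm"]] / cfg@tissueMeansT2w[["gm"]],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("classic ratio divides voxelwise with a denominator guard", {
  dims <- c(8L, 8L, 8L)
  brain <- array(TRUE, dims)
  t1 <- array(430, dims)
  t2 <- array(40, dims)
  t2[1, 1, 1] <- 0
  maps <- computeT1T2Ratio(imageVolume(t1, 1, "T1w"),
                           imageVolume(t2, 1, "T2w"), brain)
  expect_equal(maps@t1t2[2, 1, 1], 10.75)
  expect_false(validMask(maps)[1, 1, 1])   # guarded, not infinite
  expect_true(is.na(maps@t1t2[1, 1, 1]))

  # global gains scale every ratio voxel by a/b
  maps2 <- computeT1T2Ratio(imageVolume(2 * t1, 1, "T1w"),
                            imageVolume(0.5 * t2, 1, "T2w"), brain)
  ok <- validMask(maps) & validMask(maps2)
  expect_equal(maps2@t1t2[ok], 4 * maps@t1t2[ok], tolerance = 1e-12)
})

test_that("standardized ratio obeys its algebraic identities and range", {
  dims <- c(8L, 8L, 8L)
  brain <- array(TRUE, dims)
  t1 <- array(3, dims)
  t2 <- array(1, dims)
  maps <- computeST1T2Ratio(imageVolume(t1, 1, "T1w"),
                            imageVolume(t2, 1, "T2w"), 1, brain)
  expect_equal(unique(maps@st1t2[brain]), 0.5)   # (3-1)/(3+1)
  same <- computeST1T2Ratio(imageVolume(t1, 1, "T1w"),
                            imageVolume(t1, 1, "T2w"), 1, brain)
  expect_equal(unique(same@st1t2[brain]), 0)     # T1w == sT2
  expect_error(computeST1T2Ratio(imageVolume(t1, 1, "T1w"),
                                 imageVolume(t2, 1, "T2w"), -1, brain),
               "scaling factor")
})

test_that("standardized map is exactly gain-invariant on a rendered subject", {
  cfg <- testConfig(noiseSd = 2, biasAmplitude = 0, gainSdT1w = 0,
                    gainSdT2w = 0, seed = 73L)
  rec <- firstSubject(cfg)
  masks <- makeNAMasks(generateLabelVolume(rec, cfg))
  ren <- renderIntensityVolumes(masks, rec, cfg)
  gain <- function(vol, a) imageVolume(a * voxelData(vol), voxelSize(vol),
                                       modality(vol))
  base <- computeRatioMaps(ren$t1w, ren$t2w, masks)
  mod <- computeRatioMaps(gain(ren$t1w, 1.83), gain(ren$t2w, 0.41), masks)
  ok <- validMask(base) & validMask(mod)
  expect_lt(max(abs(mod@st1t2[ok] - base@st1t2[ok]) /
                pmax(abs(base@st1t2[ok]), 1e-12)), 1e-10)
  # while the classic ratio scales
  expect_equal(mod@t1t2[ok], (1.83 / 0.41) * base@t1t2[ok], tolerance = 1e-12)
  # range contract on valid voxels
  expect_true(all(abs(base@st1t2[ok]) < 1))
})

test_that("raising one T1w voxel raises its ratio values monotonically", {
  cfg <- cleanConfig(seed = 79L)
  rec <- firstSubject(cfg)
  masks <- makeNAMasks(generateLabelVolume(rec, cfg))
  ren <- renderIntensityVolumes(masks, rec, cfg)
  vox <- which(masks@nawm)[10]   # outside NAGM: scaling factor unchanged
  v <- voxelData(ren$t1w)
  v[vox] <- v[vox] * 1.3
  bumped <- imageVolume(v, voxelSize(ren$t1w), "T1w")
  base <- computeRatioMaps(ren$t1w, ren$t2w, masks)
  mod <- computeRatioMaps(bumped, ren$t2w, masks)
  expect_gt(mod@t1t2[vox], base@t1t2[vox])
  expect_gt(mod@st1t2[vox], base@st1t2[vox])
  other <- validMask(base); other[vox] <- FALSE
  expect_equal(mod@st1t2[other], base@st1t2[other], tolerance = 1e-12)
})

test_that("tissue medians reproduce constants and the phantom sign structure", {
  cfg <- cleanConfig(seed = 83L)
  rec <- firstSubject(cfg)
  masks <- makeNAMasks(generateLabelVolume(rec, cfg))
  ren <- renderIntensityVolumes(masks, rec, cfg)
  maps <- computeRatioMaps(ren$t1w, ren$t2w, masks)
  med <- extractTissueMedians(ren$t1w, ren$t2w, maps, masks, rec$subject_id)
  expect_equal(nrow(med), 12L)
  expect_true(all(is.finite(med$median)))
  get <- function(m, r) med$median[med$measure == m & med$region == r]
  # gray matter anchors near zero; WM positive; CSF negative
  expect_lt(abs(get("st1t2", "NAGM")), 0.01)
  expect_gt(get("st1t2", "NAWM"), 0)
  expect_lt(get("st1t2", "CSF"), 0)
  # raw medians are the configured tissue means
  expect_equal(get("T1w", "NAGM"), cfg@tissueMeansT1w[["gm"]])
  expect_equal(get("T2w", "CSF"), cfg@tissueMeansT2w[["csf"]])
})

test_that("a region with no valid voxels is a hard error", {
  dims <- c(8L, 8L, 8L)
  brain <- array(TRUE, dims)
  masks <- makeNAMasks(tissueMaskSet(
    brain,
    gm = array(rep(c(TRUE, FALSE), each = 256), dims),
    wm = array(rep(c(FALSE, TRUE), each = 256), dims),
    csf = array(FALSE, dims) | FALSE,
    lesion = array(FALSE, dims)))
  expect_error(makeNAMasks(masks), NA)
  t1 <- imageVolume(array(300, dims), 1, "T1w")
  t2 <- imageVolume(array(60, dims), 1, "T2w")
  maps <- computeRatioMaps(t1, t2, masks)
  expect_error(extractTissueMedians(t1, t2, maps, masks, "x"),
               "degenerate region")   # empty CSF
})
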