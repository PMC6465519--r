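test_that("subject table reproduces the configured cohort structure", {
  cfg <- generatorConfig(seed = 11L)  # full 47 + 47 defaults
  tab <- generateSubjectTable(cfg)
  ms <- tab[tab$group == "MS", ]
  hc <- tab[tab$group == "HC", ]

  expect_equal(nrow(tab), 94L)
  expect_equal(sum(ms$sex == "F"), 30L)
  expect_equal(sum(hc$sex == "F"), 30L)
  # pairs share sex and are age-matched within half a year
  expect_identical(ms$sex, hc$sex)
  expect_true(all(abs(ms$age - hc$age) <= 0.5 + 1e-12))
  # ages within the configured truncation range
  expect_true(all(tab$age >= 20 & tab$age <= 64))
  # MS age moments approach the configured 37.69 (9.22)
  expect_lt(abs(mean(ms$age) - 37.69), 3.5)
  expect_lt(abs(sd(ms$age) - 9.22), 3.5)
  # clinical covariates only for patients
  expect_true(all(is.na(hc$edss)) && all(is.na(hc$disease_duration_months)))
  expect_true(all(!is.na(ms$edss)) && all(ms$edss %% 0.5 == 0))
  expect_true(all(ms$edss >= 0 & ms$edss <= 6))
  # lesion volume is zero iff the count is zero
  expect_identical(tab$lesion_volume_ml == 0, tab$lesion_count == 0L)
  expect_true(all(tab$lesion_count >= 0L))
  # one blanked head size by default
  expect_equal(sum(is.na(tab$head_size_scale)), 1L)
})

test_that("subject table generation is deterministic and moment-matched", {
  cfg <- testConfig(seed = 5L)
  expect_identical(generateSubjectTable(cfg), generateSubjectTable(cfg))
  expect_false(identical(generateSubjectTable(cfg),
                         generateSubjectTable(testConfig(seed = 6L))))

  # over >= 500 MS subjects the negative binomial reproduces its moments
  big <- generatorConfig(nPerGroup = 600L, femaleCount = 300L, seed = 2L)
  counts <- generateSubjectTable(big)
  counts <- counts[counts$group == "MS", "lesion_count"]
  expect_lt(abs(mean(counts) - 59.23) / 59.23, 0.10)
  expect_lt(abs(sd(counts) - 46.75) / 46.75, 0.10)
})

test_that("degenerate lesion moments yield lesion-free subjects", {
  z <- rbind(ms = c(mean = 0, sd = 0), hc = c(mean = 0, sd = 0))
  cfg <- testConfig(nPerGroup = 2L, femaleCount = 1L,
                    lesionCountMoments = z, lesionVolumeMoments = z)
  tab <- generateSubjectTable(cfg)
  expect_true(all(tab$lesion_count == 0L))
  expect_true(all(tab$lesion_volume_ml == 0))
})

test_that("label phantom satisfies mask geometry invariants", {
  cfg <- testConfig(seed = 3L)
  rec <- firstSubject(cfg)
  masks <- generateLabelVolume(rec, cfg)
  # pairwise disjoint tissues inside the brain (validity enforces this,
  # assert explicitly on the constructed object)
  expect_true(validObject(masks))
  expect_false(any(masks@gm & masks@wm))
  expect_false(any(masks@gm & masks@csf))
  expect_false(any(masks@wm & masks@csf))
  expect_true(all(!(masks@gm | masks@wm | masks@csf | masks@lesion) | masks@brain))
  expect_true(all(masks@lesion[masks@lesion] & masks@wm[masks@lesion]))
  # determinism keyed on seed and subject id
  expect_identical(masks@lesion, generateLabelVolume(rec, cfg)@lesion)
})

test_that("lesion rasterisation matches the requested volume", {
  cfg <- testConfig(seed = 3L)
  rec <- firstSubject(cfg)
  rec$lesion_count <- 10L
  rec$lesion_volume_ml <- 5
  masks <- generateLabelVolume(rec, cfg)
  got <- sum(masks@lesion) * cfg@voxelSizeMM^3 / 1000
  expect_lt(abs(got - 5) / 5, 0.10)

  # no lesions: empty mask and NAWM == WM
  rec0 <- rec
  rec0$lesion_count <- 0L
  rec0$lesion_volume_ml <- 0
  m0 <- makeNAMasks(generateLabelVolume(rec0, cfg))
  expect_false(any(m0@lesion))
  expect_identical(m0@nawm, m0@wm)

  # infeasible volume request
  recBig <- rec
  recBig$lesion_volume_ml <- 1e4
  expect_error(generateLabelVolume(recBig, cfg), "infeasible")
})

test_that("noise-free renders implant the target NAWM standardized median", {
  for (s in c(-0.8, -0.3, 0, 0.41, 0.8)) {
    cfg <- cleanConfig(nPerGroup = 2L, femaleCount = 1L, stBaseline = s,
                       effectMS = 0, effectAge = 0, effectLesionCount = 0,
                       seed = 17L)
    rec <- firstSubject(cfg)
    med <- subjectMedians(rec, cfg, biasCorrect = FALSE)
    got <- med$median[med$measure == "st1t2" & med$region == "NAWM"]
    expect_lt(abs(got - s), 0.005)
  }
})

test_that("zero implant leaves WM T1w at the scaled-T2w level", {
  cfg <- cleanConfig(nPerGroup = 2L, femaleCount = 1L, stBaseline = 0,
                     effectMS = 0, effectAge = 0, effectLesionCount = 0,
                     seed = 19L)
  rec <- firstSubject(cfg)
  masks <- generateLabelVolume(rec, cfg)
  ren <- renderIntensityVolumes(masks, rec, cfg)
  w <- cfg@tissueMeansT1w[["gm"]] / cfg@tissueMeansT2w[["gm"]] *
    cfg@tissueMeansT2w[["wm"]]
  nawm <- masks@wm & !masks@lesion
  expect_equal(unique(voxelData(ren$t1w)[nawm]), w)
})

test_that("an out-of-range implant target is rejected", {
  cfg <- cleanConfig(nPerGroup = 2L, femaleCount = 1L, stBaseline = 0.999,
                     effectMS = 0.1, seed = 1L)
  rec <- firstSubject(cfg)
  masks <- generateLabelVolume(rec, cfg)
  expect_error(renderIntensityVolumes(masks, rec, cfg),
               "invalid effect configuration")
})

test_that("per-subject gains leave the standardized map unchanged downstream", {
  cfgOff <- cleanConfig(seed = 23L)
  cfgOn <- testConfig(noiseSd = 0, biasAmplitude = 0,
                      gainSdT1w = 0.25, gainSdT2w = 0.25, seed = 23L)
  rec <- firstSubject(cfgOff)
  masks <- makeNAMasks(generateLabelVolume(rec, cfgOff))
  a <- renderIntensityVolumes(masks, rec, cfgOff)
  b <- renderIntensityVolumes(masks, rec, cfgOn)
  expect_false(isTRUE(all.equal(b$gains, a$gains)))
  mapsA <- computeRatioMaps(a$t1w, a$t2w, masks)
  mapsB <- computeRatioMaps(b$t1w, b$t2w, masks)
  expect_equal(mapsB@st1t2, mapsA@st1t2, tolerance = 1e-10)
})

test_that("cohort NIfTI artifacts round-trip", {
  dir <- withr::local_tempdir()
  cfg <- testConfig(nPerGroup = 2L, femaleCount = 1L, gridShape = 24L,
                    voxelSizeMM = 4, seed = 31L)
  tab <- simulateCohort(cfg, dir)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  id <- tab$subject_id[1]
  t1 <- readNiftiVolume(file.path(dir, paste0(id, "_T1w.nii.gz")), "T1w")
  expect_equal(voxelSize(t1), 4)
  labels <- round(voxelData(readNiftiVolume(
    file.path(dir, paste0(id, "_labels.nii.gz")), "field")))
  masks <- labelsToMasks(labels)
  expect_identical(masks@lesion, generateLabelVolume(tab[1, ], cfg)@lesion)
})
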