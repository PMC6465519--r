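## End-to-end orchestration: simulate -> preprocess -> ratio -> statistics.

MEASURES <- c("T1w", "T2w", "t1t2", "st1t2")

#' Process one subject from label phantom to tissue medians
#'
#' Generates the subject's label phantom and intensity volumes, optionally
#' estimates and divides out a per-modality bias field, computes the ratio
#' maps and extracts the per-tissue medians.
#'
#' @param record one subject-table row.
#' @param config a [GeneratorConfig-class].
#' @param biasCorrect estimate and remove a bias field per modality.
#' @param biasDegree polynomial degree for the bias fit.
#' @param eps denominator guard forwarded to the ratio maps.
#' @return the subject's long tissue-median `data.frame`.
#' @export
subjectMedians <- function(record, config, biasCorrect = TRUE,
                           biasDegree = 2L, eps = NULL) {
  masks <- makeNAMasks(generateLabelVolume(record, config))
  ren <- renderIntensityVolumes(masks, record, config)
  t1w <- ren$t1w
  t2w <- ren$t2w
  if (biasCorrect) {
    t1w <- correctBias(t1w, estimateBiasField(t1w, masks@brain, biasDegree),
                       masks@brain)
    t2w <- correctBias(t2w, estimateBiasField(t2w, masks@brain, biasDegree),
                       masks@brain)
  }
  maps <- computeRatioMaps(t1w, t2w, masks, eps)
  extractTissueMedians(t1w, t2w, maps, masks, record$subject_id)
}

wideMedians <- function(medians) {
  medians$key <- paste(medians$measure, medians$region, sep = "_")
  w <- stats::reshape(medians[c("subject_id", "key", "median")],
                      idvar = "subject_id", timevar = "key",
                      direction = "wide")
  names(w) <- sub("^median\\.", "", names(w))
  rownames(w) <- NULL
  w
}

#' Run the cohort statistics battery on a median table
#'
#' Given the per-subject tissue medians and the subject table, computes:
#' demographic matching tests (Welch t on age, chi-square on sex, both in
#' HC-minus-MS order), the per-group NAWM coefficient of variation for the
#' classic and standardized ratios with the asymptotic CoV-equality test,
#' Welch group comparisons for every measure in NAGM and NAWM gated at the
#' Bonferroni level, the Pearson correlation between the two NAWM ratio
#' measures, and backward-stepwise covariate models (whole cohort:
#' group + age + sex-by-head-size; patients only: age, disease duration,
#' EDSS, lesion volume and count, age-by-duration, sex-by-head-size) for
#' each of the four NAWM responses.
#'
#' @param medians long tissue-median table ([subjectMedians()] rows).
#' @param subjects the subject table.
#' @param alpha Bonferroni-corrected significance gate (default 0.004).
#' @param threshold stepwise removal threshold (default 0.05).
#' @return a list with components `demographics`, `covTable`, `covTests`,
#'   `groupComparisons`, `correlation`, `stepwiseCohort`,
#'   `stepwisePatients`.
#' @export
analyzeCohortMedians <- function(medians, subjects, alpha = 0.004,
                                 threshold = 0.05) {
  w <- wideMedians(medians)
  d <- merge(subjects, w, by = "subject_id", sort = TRUE)
  d$group <- factor(d$group, levels = c("HC", "MS"))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  hc <- d[d$group == "HC", ]
  ms <- d[d$group == "MS", ]

  demographics <- list(
    age = welchT(hc$age, ms$age),
    sex = chiSquare2x2(table(d$group, d$sex))
  )

  covTable <- expand.grid(group = c("MS", "HC"), measure = c("t1t2", "st1t2"),
                          stringsAsFactors = FALSE)
  covTable$cov_percent <- mapply(function(g, m)
    coefficientOfVariation(d[d$group == g, paste0(m, "_NAWM")]),
    covTable$group, covTable$measure)
  covTests <- lapply(c(MS = "MS", HC = "HC"), function(g) {
    gd <- d[d$group == g, ]
    covEqualityTest(
      c(coefficientOfVariation(gd$t1t2_NAWM),
        coefficientOfVariation(gd$st1t2_NAWM)) / 100,
      c(nrow(gd), nrow(gd)))
  })

  gc <- expand.grid(measure = MEASURES, region = c("NAGM", "NAWM"),
                    stringsAsFactors = FALSE)
  res <- mapply(function(m, r) {
    col <- paste(m, r, sep = "_")
    unlist(welchT(hc[[col]], ms[[col]]))
  }, gc$measure, gc$region)
  gc$t <- res["t", ]
  gc$df <- res["df", ]
  gc$p_value <- res["p_value", ]
  gc$significant <- gc$p_value < alpha

  correlation <- pearsonWithAdjR2(d$t1t2_NAWM, d$st1t2_NAWM)

  responses <- paste0(MEASURES, "_NAWM")
  cohortPred <- c("group", "age", "sex:head_size_scale")
  patientPred <- c("age", "disease_duration_months", "edss",
                   "lesion_volume_ml", "lesion_count",
                   "age:disease_duration_months", "sex:head_size_scale")
  stepwiseCohort <- lapply(setNames(responses, responses), function(r)
    backwardStepwiseOLS(d, r, cohortPred, threshold))
  stepwisePatients <- lapply(setNames(responses, responses), function(r)
    backwardStepwiseOLS(ms, r, patientPred, threshold))

  list(demographics = demographics, covTable = covTable,
       covTests = covTests, groupComparisons = gc,
       correlation = correlation, stepwiseCohort = stepwiseCohort,
       stepwisePatients = stepwisePatients)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, processes every subject through preprocessing and
#' ratio mapping, and runs the statistics battery. Deterministic given the
#' config seed. Any per-model Cook's distance above 1 is reported as a
#' message.
#'
#' @param config a [GeneratorConfig-class].
#' @param biasCorrect,biasDegree,eps forwarded to [subjectMedians()].
#' @param alpha,threshold forwarded to [analyzeCohortMedians()].
#' @param outDir if non-NULL, artifacts (`subjects.tsv`, `medians.tsv`,
#'   `report.json` and table TSVs) are written there.
#' @param verbose print per-subject progress.
#' @return a [CohortReport-class].
#' @examples
#' \donttest{
#' cfg <- generatorConfig(nPerGroup = 3L, gridShape = 24L, seed = 1L)
#' rep <- runCohortPipeline(cfg)
#' }
#' @export
runCohortPipeline <- function(config, biasCorrect = TRUE, biasDegree = 2L,
                              eps = NULL, alpha = 0.004, threshold = 0.05,
                              outDir = NULL, verbose = FALSE) {
  validObject(config)
  subjects <- generateSubjectTable(config)
  medians <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    rec <- subjects[i, ]
    medians[[i]] <- tryCatch(
      subjectMedians(rec, config, biasCorrect, biasDegree, eps),
      error = function(e) stop(sprintf("stage ratio failed for subject %s: %s",
                                       rec$subject_id, conditionMessage(e)),
                               call. = FALSE))
    if (verbose) message("processed ", rec$subject_id)
  }
  medians <- do.call(rbind, medians)
  stats <- analyzeCohortMedians(medians, subjects, alpha, threshold)
  for (nm in names(stats$stepwiseCohort)) {
    mc <- max(vapply(stats$stepwiseCohort[[nm]]@path,
                     function(m) m$max_cooks, numeric(1)))
    if (mc > 1) message(sprintf("influence flag: %s cohort model max Cook's distance %.2f > 1",
                                nm, mc))
  }
  report <- new("CohortReport",
                subjects = subjects, medians = medians,
                demographics = stats$demographics, covTable = stats$covTable,
                covTests = stats$covTests,
                groupComparisons = stats$groupComparisons,
                correlation = stats$correlation,
                stepwiseCohort = stats$stepwiseCohort,
                stepwisePatients = stats$stepwisePatients,
                settings = list(seed = config@seed, alpha = alpha,
                                threshold = threshold,
                                biasCorrect = biasCorrect,
                                biasDegree = biasDegree,
                                groupOrder = "HC-MS",
                                gridShape = config@gridShape,
                                nPerGroup = config@nPerGroup))
  if (!is.null(outDir)) writeCohortReport(report, outDir)
  report
}

stepwiseToList <- function(sf) {
  list(response = sf@response, selected = sf@selected,
       threshold = sf@threshold,
       models = lapply(sf@path, function(m) {
         m$coefficients <- as.list(setNames(m$coefficients$estimate,
                                            m$coefficients$name))
         m
       }))
}

#' Write a cohort report to disk
#'
#' Emits `subjects.tsv`, `medians.tsv`, `cov_table.tsv`,
#' `group_comparisons.tsv` and a machine-readable `report.json` holding
#' every statistic (p-values at machine precision). Byte-identical across
#' re-runs with the same config and seed.
#'
#' @param report a [CohortReport-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writeCohortReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report@subjects, "subjects.tsv")
  wt(report@medians, "medians.tsv")
  wt(report@covTable, "cov_table.tsv")
  wt(report@groupComparisons, "group_comparisons.tsv")
  payload <- list(
    settings = report@settings,
    demographics = report@demographics,
    cov_table = report@covTable,
    cov_tests = lapply(report@covTests, unclass),
    group_comparisons = report@groupComparisons,
    correlation = report@correlation,
    stepwise_cohort = lapply(report@stepwiseCohort, stepwiseToList),
    stepwise_patients = lapply(report@stepwisePatients, stepwiseToList)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Re-run the statistics stage from saved artifacts
#'
#' Resumes the pipeline from a `medians.tsv` / `subjects.tsv` pair,
#' producing the same downstream results as a full run.
#'
#' @param mediansFile path to the long medians TSV.
#' @param subjectsFile path to the subject TSV.
#' @inheritParams analyzeCohortMedians
#' @return the [analyzeCohortMedians()] result list.
#' @export
resumeCohortStats <- function(mediansFile, subjectsFile, alpha = 0.004,
                              threshold = 0.05) {
  medians <- utils::read.delim(mediansFile, stringsAsFactors = FALSE)
  subjects <- utils::read.delim(subjectsFile, stringsAsFactors = FALSE)
  analyzeCohortMedians(medians, subjects, alpha, threshold)
}
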