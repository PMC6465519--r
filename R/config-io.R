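## YAML configuration for command-line runs.

momentsMatrix <- function(x) {
  rbind(ms = c(mean = x$ms[[1]], sd = x$ms[[2]]),
        hc = c(mean = x$hc[[1]], sd = x$hc[[2]]))
}

#' Read a generator configuration from YAML
#'
#' Keys mirror the [generatorConfig()] arguments (snake_case accepted);
#' lesion moment matrices are given as `{ms: [mean, sd], hc: [mean, sd]}`.
#' A seed must be present in the file or supplied via `seed`.
#'
#' @param file path to a YAML file (missing keys keep their defaults).
#' @param seed optional integer overriding the file's seed.
#' @return a [GeneratorConfig-class].
#' @export
readGeneratorConfig <- function(file, seed = NULL) {
  raw <- if (is.null(file)) list() else yaml::read_yaml(file)
  # map keys onto generatorConfig() arguments ignoring case/underscores,
  # so snake_case YAML (voxel_size_mm) hits camelCase formals (voxelSizeMM)
  formalsNm <- names(formals(generatorConfig))
  norm <- function(s) tolower(gsub("_", "", s))
  hit <- match(norm(names(raw)), norm(formalsNm))
  if (anyNA(hit))
    stop("unknown config key(s): ",
         paste(names(raw)[is.na(hit)], collapse = ", "))
  names(raw) <- formalsNm[hit]
  for (k in c("lesionCountMoments", "lesionVolumeMoments"))
    if (!is.null(raw[[k]])) raw[[k]] <- momentsMatrix(raw[[k]])
  for (k in c("tissueMeansT1w", "tissueMeansT2w"))
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  for (k in c("ageRange", "edssRange", "durationMoments"))
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  if (!is.null(raw$gridShape)) raw$gridShape <- as.integer(unlist(raw$gridShape))
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  if (is.null(raw$seed)) stop("a seed is mandatory: set it in the config file or pass --seed")
  do.call(generatorConfig, raw)
}
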