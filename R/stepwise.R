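## Backward stepwise OLS with AIC selection and influence diagnostics.

#' Maximum Cook's distance of a fitted model
#'
#' A maximum above 1 indicates an observation that is overly influencing
#' the fit; the cohort pipeline flags such models.
#'
#' @param model a fitted `lm`.
#' @return the maximum Cook's distance over observations.
#' @export
cooksDistanceMax <- function(model) {
  d <- cooks.distance(model)
  max(d[is.finite(d)])
}

summariseLm <- function(fit, termLabels) {
  sm <- summary(fit)
  co <- sm$coefficients
  fs <- sm$fstatistic
  list(
    terms = termLabels,
    coefficients = data.frame(
      name = rownames(co), estimate = co[, "Estimate"],
      p = co[, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE),
    adj_r2 = sm$adj.r.squared,
    residual_se = sm$sigma,
    f_statistic = if (is.null(fs)) NA_real_ else unname(fs["value"]),
    f_df = if (is.null(fs)) c(NA_real_, NA_real_)
           else unname(fs[c("numdf", "dendf")]),
    aic = AIC(fit),
    n = stats::nobs(fit),
    max_cooks = cooksDistanceMax(fit)
  )
}

#' Backward stepwise ordinary least squares
#'
#' Fits the full model, then repeatedly removes the least significant term
#' and refits until every remaining term is significant at `threshold`.
#' Term significance is judged by the largest p-value among the term's
#' coefficients, so multi-coefficient terms (such as a sex-by-head-size
#' interaction entering as one coefficient per sex, with no sex main
#' effect) are kept or removed as a unit. Marginality is respected: a main
#' effect is not removed while a retained interaction involves its
#' variable. Each model along the path is
#' refitted on the complete cases of its own variables (listwise deletion
#' per model), so observation counts may grow as covariates with missing
#' values drop out. Every visited model's AIC is recorded and the
#' minimum-AIC model is selected.
#'
#' @param data a `data.frame`.
#' @param response response column name.
#' @param predictors character vector of model terms, e.g.
#'   `c("group", "age", "sex:head_size_scale")`; interaction terms use
#'   formula syntax.
#' @param threshold removal p-value threshold (default 0.05; the
#'   Bonferroni level applies to final inference, not to removal).
#' @return a [StepwiseFit-class].
#' @export
backwardStepwiseOLS <- function(data, response, predictors,
                                threshold = 0.05) {
  stopifnot(response %in% names(data))
  current <- predictors
  path <- list()
  repeat {
    rhs <- if (length(current)) paste(current, collapse = " + ") else "1"
    f <- as.formula(paste(response, "~", rhs))
    vars <- all.vars(f)
    cc <- data[complete.cases(data[vars]), vars, drop = FALSE]
    fit <- lm(f, data = cc)
    if (any(is.na(coef(fit))))
      stop("collinear design: rank-deficient fit for ", deparse(f))
    if (stats::nobs(fit) < length(coef(fit)) + 2L)
      stop("too few complete cases for ", deparse(f))
    rec <- summariseLm(fit, current)
    path[[length(path) + 1L]] <- rec
    if (!length(current)) break
    labels <- attr(terms(fit), "term.labels")
    asgn <- fit$assign
    co <- summary(fit)$coefficients
    termP <- vapply(seq_along(labels), function(i)
      max(co[asgn == i, "Pr(>|t|)"]), numeric(1))
    # marginality: a main effect stays while a retained interaction
    # involves its variable(s)
    vsets <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
    removable <- vapply(seq_along(labels), function(i)
      !any(vapply(seq_along(labels), function(j)
        j != i && all(vsets[[i]] %in% vsets[[j]]), logical(1))), logical(1))
    cand <- which(removable & termP >= threshold)
    if (!length(cand)) break
    worst <- cand[which.max(termP[cand])]
    # match on the variable set: terms() may reorder interaction labels
    key <- vapply(lapply(strsplit(current, ":", fixed = TRUE), sort),
                  paste, character(1), collapse = ":")
    current <- current[key != paste(vsets[[worst]], collapse = ":")]
  }
  new("StepwiseFit", response = response, path = path,
      selected = which.min(vapply(path, function(m) m$aic, numeric(1))),
      threshold = threshold)
}
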