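#' @include AllClasses.R survival-core.R model-building.R
NULL

## ---------------------------------------------------------------------------
## Internal LOOCV engine on raw matrices (hot path for permutation tests)
## ---------------------------------------------------------------------------

## X: complete numeric matrix (candidates + mandatory columns),
## eligible: logical per column (mandatory = FALSE), train_time/train_event
## define model building; returns per-subject group (TRUE = high) and PI.
## Ties at the training median go to high risk (PI >= median).
.loocv_core <- function(X, time, event, eligible, p_remove, efron = TRUE,
                        collectModels = FALSE) {
  n <- nrow(X)
  if (length(eligible) == 1L) eligible <- rep(eligible, ncol(X))
  nms <- colnames(X)
  res <- .cox_loocv_cpp(t(X), time, as.integer(event),
                        as.integer(order(time) - 1L), eligible,
                        as.integer(rank(nms)), p_remove, efron,
                        1e-8, 40L, 12, collectModels)
  models <- NULL
  if (collectModels)
    models <- lapply(res$models, function(m)
      list(variables = nms[m$selected + 1L],
           coefficients = as.numeric(m$beta)))
  list(high = as.logical(res$high), pi = as.numeric(res$pi),
       models = models)
}

## assemble a CvRiskResult from raw pieces
.cv_result <- function(ids, pi, high, models, evalTime, evalEvent, endpoint) {
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  if (nlevels(droplevels(grp)) < 2L)
    stop("cross-validated classification produced a single risk group; ",
         "log-rank comparison undefined")
  svLow <- survivalData(evalTime[!high], evalEvent[!high], ids[!high],
                        endpoint)
  svHigh <- survivalData(evalTime[high], evalEvent[high], ids[high],
                         endpoint)
  sv <- survivalData(evalTime, evalEvent, ids, endpoint)
  lr <- logRank(sv, grp)
  kmL <- kaplanMeier(svLow); kmH <- kaplanMeier(svHigh)
  new("CvRiskResult", subjectIds = ids, pi = pi, riskGroup = grp,
      foldModels = if (is.null(models)) list() else models,
      kmLow = kmL, kmHigh = kmH, logRank = lr,
      groupSizes = c(low = sum(!high), high = sum(high)),
      eventCounts = c(low = sum(evalEvent[!high]),
                      high = sum(evalEvent[high])),
      medianSurvival = c(low = kmMedian(kmL), high = kmMedian(kmH)),
      endpoint = endpoint)
}

## shared front end: validates inputs, applies listwise-complete handling,
## returns the raw matrices the engines consume
.cv_prepare <- function(coded, surv, mandatory) {
  stopifnot(is(coded, "CodedMatrix"), is(surv, "SurvivalData"))
  V <- coded@values
  if (nrow(V) != length(surv@time))
    stop("coded matrix and survival data are not row-aligned")
  M <- NULL
  if (!is.null(mandatory)) {
    M <- as.matrix(mandatory)
    if (is.null(colnames(M))) colnames(M) <- paste0("covariate",
                                                    seq_len(ncol(M)))
    if (nrow(M) != nrow(V)) stop("mandatory covariates not row-aligned")
  }
  X <- cbind(V, M)
  eligible <- c(rep(TRUE, ncol(V)), rep(FALSE, if (is.null(M)) 0 else ncol(M)))
  use <- stats::complete.cases(X)
  if (any(!use))
    warning(sum(!use), " subject(s) with missing entries excluded listwise",
            call. = FALSE)
  keep <- .screen_columns(X[use, , drop = FALSE], warnDrops = FALSE,
                          protect = if (is.null(M)) character(0)
                                    else colnames(M))
  list(X = X[use, keep, drop = FALSE],
       eligible = eligible[match(keep, colnames(X))], use = use)
}

#' Leave-one-out cross-validated survival risk classification
#'
#' For each subject in turn, the entire signature-building procedure —
#' backward elimination included — is repeated on the remaining n - 1
#' subjects; the held-out subject is assigned to the high-risk group iff its
#' prognostic index under the fold's model is at or above the median
#' training prognostic index. Because each subject's risk group comes from a
#' model that never saw that subject, the pooled Kaplan-Meier curves of the
#' two groups are unbiased, and their log-rank statistic (LR_d) honestly
#' measures the predictive value of the genotype data.
#'
#' A fold whose model eliminates every variable assigns prognostic index 0
#' to everyone; the held-out subject then lands in the high-risk group by
#' the >= rule.
#'
#' @param coded a [CodedMatrix-class] of candidate variables.
#' @param surv a [SurvivalData-class] row-aligned with \code{coded}.
#' @param mandatory optional covariate column(s) (e.g. stage) forced into
#'   every fold model.
#' @param pRemove backward-elimination stay threshold (default 0.10).
#' @param ties tie-handling method.
#' @param collectModels keep each fold's selected variables and
#'   coefficients (memory permitting).
#' @return a [CvRiskResult-class].
#' @export
loocvRiskClassify <- function(coded, surv, mandatory = NULL, pRemove = 0.10,
                              ties = c("efron", "breslow"),
                              collectModels = FALSE) {
  ties <- match.arg(ties)
  prep <- .cv_prepare(coded, surv, mandatory)
  n <- nrow(prep$X)
  if (n < 10L) stop("LOOCV requires at least 10 subjects")
  time <- surv@time[prep$use]; event <- surv@event[prep$use]
  ids <- surv@subjectIds[prep$use]
  res <- .loocv_core(prep$X, time, event, prep$eligible, pRemove,
                     efron = ties == "efron", collectModels = collectModels)
  .cv_result(ids, res$pi, res$high, res$models, time, event, surv@endpoint)
}

#' Resubstitution (non-cross-validated) risk classification
#'
#' Builds one signature on the full data, splits subjects at the median of
#' their own prognostic indices (>= median = high risk) and computes the
#' log-rank statistic between the groups. This statistic is optimistically
#' biased — the same subjects selected the markers being evaluated — and is
#' provided as the contrast for the cross-validated statistic.
#'
#' @inheritParams loocvRiskClassify
#' @return a [CvRiskResult-class] (foldModels holds the single full-data
#'   model).
#' @export
resubstitutionRiskClassify <- function(coded, surv, mandatory = NULL,
                                       pRemove = 0.10,
                                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  prep <- .cv_prepare(coded, surv, mandatory)
  time <- surv@time[prep$use]; event <- surv@event[prep$use]
  ids <- surv@subjectIds[prep$use]
  res <- .backward_core(prep$X, time, event, prep$eligible, pRemove,
                        efron = ties == "efron")
  pi <- if (res$empty) numeric(length(ids))
        else as.numeric(prep$X[, res$variables, drop = FALSE] %*% res$beta)
  high <- pi >= stats::median(pi)
  .cv_result(ids, pi, high,
             list(list(variables = res$variables,
                       coefficients = as.numeric(res$beta))),
             time, event, surv@endpoint)
}

#' Cross-endpoint validation: build on OS, evaluate on RFS
#'
#' Runs the identical leave-one-out loop as [loocvRiskClassify()] with model
#' building and the median split computed from the training endpoint
#' (overall survival), but computes the final Kaplan-Meier curves and
#' log-rank statistic of the cross-validated groups against the test
#' endpoint (relapse-free survival).
#'
#' @param coded a [CodedMatrix-class].
#' @param trainSurv the endpoint used to build every fold model (OS).
#' @param testSurv the endpoint the risk groups are evaluated on (RFS);
#'   row-aligned with \code{trainSurv}.
#' @inheritParams loocvRiskClassify
#' @return a [CvRiskResult-class] evaluated on the test endpoint.
#' @export
crossEndpointValidate <- function(coded, trainSurv, testSurv,
                                  mandatory = NULL, pRemove = 0.10,
                                  ties = c("efron", "breslow"),
                                  collectModels = FALSE) {
  ties <- match.arg(ties)
  stopifnot(is(testSurv, "SurvivalData"))
  if (length(testSurv@time) != length(trainSurv@time))
    stop("train and test endpoints are not row-aligned")
  prep <- .cv_prepare(coded, trainSurv, mandatory)
  n <- nrow(prep$X)
  if (n < 10L) stop("LOOCV requires at least 10 subjects")
  time <- trainSurv@time[prep$use]; event <- trainSurv@event[prep$use]
  ids <- trainSurv@subjectIds[prep$use]
  res <- .loocv_core(prep$X, time, event, prep$eligible, pRemove,
                     efron = ties == "efron", collectModels = collectModels)
  .cv_result(ids, res$pi, res$high, res$models,
             testSurv@time[prep$use], testSurv@event[prep$use],
             testSurv@endpoint)
}

#' Run summary of a cross-validated risk classification
#'
#' @param result a [CvRiskResult-class].
#' @return one-row data.frame: group sizes, event counts, median survival
#'   per group, LR_d and its asymptotic p.
#' @export
cvRiskSummary <- function(result) {
  stopifnot(is(result, "CvRiskResult"))
  data.frame(endpoint = result@endpoint,
             nLow = result@groupSizes[["low"]],
             eventsLow = result@eventCounts[["low"]],
             medianLow = result@medianSurvival[["low"]],
             nHigh = result@groupSizes[["high"]],
             eventsHigh = result@eventCounts[["high"]],
             medianHigh = result@medianSurvival[["high"]],
             LRd = result@logRank@statistic,
             logRankP = result@logRank@pValue)
}
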