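#' @include AllClasses.R survival-core.R
NULL

#' Time-dependent ROC curve from censored survival data
#'
#' Cumulative-case / dynamic-control ROC of a continuous marker M at horizon
#' t: sensitivity(c, t) = P(M > c | T <= t) and specificity(c, t) =
#' P(M <= c | T > t), estimated by Bayes' rule from Kaplan-Meier components:
#' \deqn{TP(c,t) = [1 - S(t | M > c)] P(M > c) / [1 - S(t)]}
#' \deqn{FP(c,t) = S(t | M > c) P(M > c) / S(t)}
#' where S is the overall KM estimate, S(t | M > c) the KM estimate within
#' the stratum above the threshold, and P(M > c) the empirical exceedance
#' fraction. The threshold grid is the set of midpoints between consecutive
#' unique marker values with -Inf/Inf anchors, so the curve is anchored at
#' (0,0) and (1,1). Because the KM-based estimator need not be monotone,
#' estimates are clipped to [0,1] and made non-decreasing along the
#' descending threshold sweep by cumulative maximum (disable with
#' \code{correct = FALSE} for diagnostic output). AUC(t) is the trapezoidal
#' area under the (FP, TP) curve; with no censoring it reduces exactly to
#' the Mann-Whitney AUC between subjects with T <= t and T > t.
#'
#' @param marker numeric marker per subject (higher = predicted earlier
#'   event), e.g. a prognostic index.
#' @param surv a [SurvivalData-class] aligned with \code{marker}.
#' @param t evaluation horizon, months; there must be at least one observed
#'   event by t and at least one subject still at risk beyond t.
#' @param correct apply clipping and the monotone correction (default TRUE).
#' @return a [TimeROC-class].
#' @export
timeDependentROC <- function(marker, surv, t, correct = TRUE) {
  stopifnot(is(surv, "SurvivalData"))
  marker <- as.numeric(marker)
  if (length(marker) != length(surv@time))
    stop("marker and survival data are not aligned")
  if (anyNA(marker)) stop("marker contains missing values")
  if (t <= 0) stop("evaluation time must be positive")
  if (t > max(surv@time))
    stop("evaluation time lies beyond the last follow-up")
  if (!any(surv@time <= t & surv@event == 1L))
    stop("no events observed by the evaluation time; sensitivity undefined")
  if (!any(surv@time > t))
    stop("no subjects at risk beyond the evaluation time")

  St <- kmSurvivalAt(kaplanMeier(surv), t)
  if (1 - St <= 0) stop("overall KM estimate puts no mass before t")
  if (St <= 0) stop("overall KM estimate is zero at t; specificity undefined")

  u <- sort(unique(marker))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thr <- c(Inf, rev(mids), -Inf)   # descending: curve runs (0,0) -> (1,1)
  tp <- fp <- numeric(length(thr))
  for (k in seq_along(thr)) {
    sel <- marker > thr[k]
    pExceed <- mean(sel)
    if (!any(sel)) { tp[k] <- 0; fp[k] <- 0; next }
    Sc <- kmSurvivalAt(kaplanMeier(survivalData(surv@time[sel],
                                                surv@event[sel])), t)
    tp[k] <- (1 - Sc) * pExceed / (1 - St)
    fp[k] <- Sc * pExceed / St
  }
  if (correct) {
    tp <- pmin(pmax(tp, 0), 1)
    fp <- pmin(pmax(fp, 0), 1)
    tp <- cummax(tp)
    fp <- cummax(fp)
  }
  o <- order(fp, tp)
  auc <- sum(diff(fp[o]) * (tp[o][-1] + tp[o][-length(tp)]) / 2)
  new("TimeROC", time = t, thresholds = thr, tp = tp, fp = fp, auc = auc,
      corrected = correct)
}

#' AUC(t) over a set of horizons
#'
#' Applies [timeDependentROC()] at each requested time; times whose
#' preconditions fail are reported with the reason rather than erroring.
#'
#' @param marker numeric marker per subject.
#' @param surv a [SurvivalData-class].
#' @param times evaluation horizons, months.
#' @param correct passed to [timeDependentROC()].
#' @return data.frame with columns time, auc, skipped, reason.
#' @export
aucTimeline <- function(marker, surv, times, correct = TRUE) {
  if (!length(times)) stop("empty time list")
  rows <- lapply(times, function(t) {
    r <- tryCatch(timeDependentROC(marker, surv, t, correct = correct),
                  error = function(e) conditionMessage(e))
    if (is.character(r))
      data.frame(time = t, auc = NA_real_, skipped = TRUE, reason = r)
    else
      data.frame(time = t, auc = r@auc, skipped = FALSE, reason = "")
  })
  do.call(rbind, rows)
}

#' Export a time-dependent ROC curve as a table
#'
#' @param roc a [TimeROC-class].
#' @return data.frame with threshold, fp, tp.
#' @export
rocTable <- function(roc) {
  data.frame(threshold = roc@thresholds, fp = roc@fp, tp = roc@tp)
}
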