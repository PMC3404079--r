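#' @include AllClasses.R
NULL

#' Construct a SurvivalData object
#'
#' @param time non-negative follow-up times, months.
#' @param event event indicators (1 = event, 0 = censored).
#' @param subjectIds optional subject labels (default "S1", "S2", ...).
#' @param endpoint endpoint label, e.g. "OS" or "RFS".
#' @return a [SurvivalData-class] object.
#' @examples
#' survivalData(c(5, 8, 12), c(1, 0, 1))
#' @export
survivalData <- function(time, event, subjectIds = NULL, endpoint = "OS") {
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_along(time))
  new("SurvivalData", subjectIds = as.character(subjectIds),
      time = as.numeric(time), event = as.integer(event),
      endpoint = endpoint)
}

## Internal: (time, event) -> per-distinct-event-time counts.
## Censored subjects tied with an event time remain at risk at that time.
.km_counts <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  if (!length(et))
    return(list(time = numeric(), nRisk = numeric(), nEvent = numeric()))
  nRisk <- vapply(et, function(t) sum(time >= t), numeric(1))
  nEvent <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  list(time = et, nRisk = nRisk, nEvent = nEvent)
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survivor function from right-censored data. Censored-only
#' times enter the risk sets but contribute no factor to the product.
#'
#' @param surv a [SurvivalData-class] object.
#' @return a [KMCurve-class] with S(t) at each distinct event time.
#' @examples
#' km <- kaplanMeier(survivalData(c(5, 8, 12, 13, 18), c(1, 0, 1, 0, 1)))
#' kmSurvivalAt(km, 12)   # 0.5333
#' @export
kaplanMeier <- function(surv) {
  stopifnot(is(surv, "SurvivalData"))
  cc <- .km_counts(surv@time, surv@event)
  s <- cumprod(1 - cc$nEvent / cc$nRisk)
  new("KMCurve", time = cc$time, surv = s, nRisk = cc$nRisk,
      nEvent = cc$nEvent, n = length(surv@time))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [KMCurve-class].
#' @param t times at which to read off S(t); S = 1 before the first event.
#' @return numeric vector of survival estimates.
#' @export
kmSurvivalAt <- function(km, t) {
  if (!length(km@time)) return(rep(1, length(t)))
  idx <- findInterval(t, km@time)
  ifelse(idx == 0, 1, km@surv[pmax(idx, 1)])
}

#' Kaplan-Meier median survival
#'
#' Smallest event time with S(t) <= 0.5, or NA when the curve never reaches
#' 0.5 ("median not reached").
#'
#' @param km a [KMCurve-class].
#' @return numeric scalar (months) or NA.
#' @export
kmMedian <- function(km) {
  hit <- which(km@surv <= 0.5 + 1e-12)
  if (!length(hit)) NA_real_ else km@time[hit[1]]
}

#' Export a Kaplan-Meier curve as a table
#'
#' @param km a [KMCurve-class].
#' @return data.frame with time, nRisk, nEvent, surv.
#' @export
kmTable <- function(km) {
  data.frame(time = km@time, nRisk = km@nRisk, nEvent = km@nEvent,
             surv = km@surv)
}

## Internal two-sample log-rank on raw vectors; groups: logical (TRUE = group B)
.log_rank_raw <- function(time, event, groupB) {
  et <- sort(unique(time[event == 1]))
  O <- sum(event == 1 & groupB)
  E <- 0; V <- 0
  for (t in et) {
    atRisk <- time >= t
    n <- sum(atRisk); nB <- sum(atRisk & groupB)
    d <- sum(time == t & event == 1)
    E <- E + d * nB / n
    if (n > 1) V <- V + d * (nB / n) * (1 - nB / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, O = O, E = E, V = V)
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square with hypergeometric variance, 1 df.
#'
#' @param surv a [SurvivalData-class].
#' @param groups binary labels (two levels), aligned with subjects.
#' @return a [LogRankResult-class].
#' @examples
#' sv <- survivalData(c(1, 3, 2, 4), c(1, 1, 1, 1))
#' logRank(sv, c("A", "A", "B", "B"))  # chi-square 8/13
#' @export
logRank <- function(surv, groups) {
  stopifnot(is(surv, "SurvivalData"))
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L)
    stop("log-rank comparison requires exactly two non-empty groups")
  g <- droplevels(g)
  isB <- g == levels(g)[2]
  lr <- .log_rank_raw(surv@time, surv@event, isB)
  totE <- sum(surv@event)
  obs <- c(totE - lr$O, lr$O)
  expd <- c(totE - lr$E, lr$E)
  names(obs) <- names(expd) <- levels(g)
  p <- stats::pchisq(lr$statistic, df = 1, lower.tail = FALSE)
  new("LogRankResult", statistic = lr$statistic, pValue = max(p, 1e-300),
      observed = obs, expected = expd,
      n = setNames(as.integer(table(g)), levels(g)))
}

## ---------------------------------------------------------------------------
## Cox fitting
## ---------------------------------------------------------------------------

## Internal fast path: X already a numeric matrix with no NA, rows in
## arbitrary order; ord = order(time) may be supplied to skip the sort.
.cox_fit_raw <- function(X, time, event, efron = TRUE, init = NULL,
                         tol = 1e-8, maxIter = 100L, ord = NULL,
                         betaBound = 20) {
  if (is.null(ord)) ord <- order(time)
  Xs <- t(X[ord, , drop = FALSE])   # fitter wants one column per subject
  ts <- time[ord]
  ev <- as.integer(event[ord])
  if (is.null(init)) init <- numeric(ncol(X))
  .cox_fit_cpp(Xs, ts, ev, init, efron, tol, maxIter, betaBound)
}

.wald_from_fit <- function(fit, nms) {
  beta <- as.numeric(fit$beta)
  se <- sqrt(pmax(diag(as.matrix(fit$vcov)), 0))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- NA_real_
  p[is.finite(p) & p < 1e-300] <- 1e-300
  list(beta = setNames(beta, nms), se = setNames(se, nms),
       z = setNames(z, nms), p = setNames(p, nms))
}

#' Fit a Cox proportional hazards model
#'
#' Newton-type maximization of the log partial likelihood with the Efron
#' (default) or Breslow tie correction, converging when the score's maximum
#' absolute component falls below \code{tol} (default 1e-8) within
#' \code{maxIter} iterations. Standard errors come from the observed
#' information; Wald 95\% intervals are exp(beta +/- 1.96 se).
#'
#' @param X numeric design matrix (subjects x variables) with column names;
#'   no missing entries, no constant columns.
#' @param surv a [SurvivalData-class] row-aligned with \code{X}.
#' @param ties "efron" or "breslow".
#' @param tol convergence tolerance on the score sup-norm.
#' @param maxIter Newton iteration cap.
#' @return a [CoxFit-class].
#' @examples
#' sv <- survivalData(c(2, 4, 6, 8, 11, 13), c(1, 1, 0, 1, 1, 0))
#' X <- cbind(marker = c(1, 1, 0, 0, 1, 0))
#' fitCox(X, sv)
#' @export
fitCox <- function(X, surv, ties = c("efron", "breslow"), tol = 1e-8,
                   maxIter = 100L) {
  ties <- match.arg(ties)
  stopifnot(is(surv, "SurvivalData"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(surv@time))
    stop("design matrix and survival data are not row-aligned")
  if (anyNA(X))
    stop("missing entries in the design matrix; apply listwise handling first")
  sds <- apply(X, 2, function(v) max(v) - min(v))
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  if (sum(surv@event) == 0) stop("no events in the survival data")
  fit <- .cox_fit_raw(X, surv@time, surv@event, efron = ties == "efron",
                      tol = tol, maxIter = as.integer(maxIter))
  if (fit$diverged > 0)
    stop("monotone likelihood: coefficient for '",
         colnames(X)[fit$diverged], "' diverged beyond bound")
  if (fit$singular)
    stop("non-identifiable fit (singular information); check for collinear columns")
  if (!fit$converged)
    stop("Cox fit did not converge in ", maxIter,
         " iterations (score sup-norm ", signif(fit$score_norm, 3), ")")
  w <- .wald_from_fit(fit, colnames(X))
  new("CoxFit", coefficients = w$beta, se = w$se, z = w$z, p = w$p,
      hr = exp(w$beta), ciLower = exp(w$beta - 1.96 * w$se),
      ciUpper = exp(w$beta + 1.96 * w$se), logLik = fit$loglik,
      logLikNull = fit$loglik_null, iterations = as.integer(fit$iter),
      converged = fit$converged, ties = ties, n = nrow(X),
      nEvent = sum(surv@event))
}
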