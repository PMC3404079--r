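#' @include AllClasses.R survival-core.R
NULL

#' Univariate Cox screening of coded variables
#'
#' Fits one single-covariate Cox model per variable (subjects with a missing
#' entry for that variable are excluded pairwise) and reports Wald p, HR and
#' 95\% CI for every variable, sorted by p. Variables whose fit fails
#' (monotone likelihood or non-convergence) are reported with
#' \code{fitFailed = TRUE}, never dropped silently.
#'
#' @param coded a [CodedMatrix-class] (normally frequency-filtered).
#' @param surv a [SurvivalData-class] row-aligned with \code{coded}.
#' @param alpha significance level for the \code{significant} flag.
#' @param ties tie-handling method passed to the Cox fitter.
#' @return a [UnivariateReport-class].
#' @export
univariateScreen <- function(coded, surv, alpha = 0.05,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is(coded, "CodedMatrix"), is(surv, "SurvivalData"))
  V <- coded@values
  if (nrow(V) != length(surv@time))
    stop("coded matrix and survival data are not row-aligned")
  efron <- ties == "efron"
  rows <- lapply(colnames(V), function(nm) {
    x <- V[, nm]
    use <- !is.na(x)
    out <- data.frame(variable = nm, p = NA_real_, hr = NA_real_,
                      ciLower = NA_real_, ciUpper = NA_real_,
                      nUsed = sum(use), significant = FALSE,
                      fitFailed = TRUE, stringsAsFactors = FALSE)
    xs <- x[use]
    if (length(unique(xs)) < 2L || sum(surv@event[use]) == 0L) return(out)
    fit <- .cox_fit_raw(cbind(xs), surv@time[use], surv@event[use],
                        efron = efron)
    if (fit$diverged > 0 || fit$singular || !fit$converged) return(out)
    w <- .wald_from_fit(fit, nm)
    out$p <- w$p; out$hr <- exp(w$beta)
    out$ciLower <- exp(w$beta - 1.96 * w$se)
    out$ciUpper <- exp(w$beta + 1.96 * w$se)
    out$significant <- is.finite(w$p) && w$p < alpha
    out$fitFailed <- FALSE
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p, tab$variable), ]
  rownames(tab) <- NULL
  new("UnivariateReport", table = tab, alpha = alpha)
}

## ---------------------------------------------------------------------------
## Backward elimination core (internal, operates on raw matrices)
## ---------------------------------------------------------------------------

## Removes non-identifiable columns before a Cox fit: constants, duplicates
## and exact linear dependencies. Because the Cox partial likelihood is
## invariant to adding a constant to the linear predictor, a set of columns
## whose linear combination is constant (e.g. the three genotype indicators
## of one SNP, which sum to 1) is aliased; the screen keeps columns in order
## of increasing carrier frequency so the most frequent member of an aliased
## set — the natural reference category — is the one dropped. Columns named
## in 'protect' (mandatory covariates) are screened first and thus always
## kept when identifiable.
.screen_columns <- function(X, warnDrops = TRUE, protect = character(0)) {
  nms <- colnames(X)
  rng <- apply(X, 2, function(v) max(v) - min(v))
  keep <- rng > 0
  idx <- which(keep)
  if (length(idx) > 1) {
    prio <- order(!(nms[idx] %in% protect), colMeans(X[, idx, drop = FALSE]),
                  nms[idx])
    ord <- idx[prio]
    n <- nrow(X)
    Q <- matrix(1 / sqrt(n), n, 1)   # intercept direction
    for (j in ord) {
      v <- X[, j]
      r <- v - Q %*% crossprod(Q, v)
      nr2 <- sum(r^2)
      if (nr2 > 1e-12 * max(sum(v^2), 1)) {
        Q <- cbind(Q, r / sqrt(nr2))
      } else {
        keep[j] <- FALSE
      }
    }
  }
  dropped <- nms[!keep]
  if (length(dropped) && warnDrops)
    warning("dropping non-identifiable column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  nms[keep]
}

## Backward elimination on complete-case raw data (C++ engine).
## eligible: logical per column; mandatory columns have eligible = FALSE and
## are never removed. Tie rule: among eligible variables sharing the maximal
## Wald p, remove the lexicographically last name. Columns whose fit is
## non-identifiable or divergent are dropped with a warning.
.backward_core <- function(X, time, event, eligible, p_remove,
                           efron = TRUE, ord = NULL) {
  if (is.null(ord)) ord <- order(time)
  nms <- colnames(X)
  res <- .cox_backward_cpp(t(X[ord, , drop = FALSE]), time[ord],
                           as.integer(event[ord]), eligible,
                           as.integer(rank(nms)), p_remove, efron,
                           1e-8, 40L, 12)
  if (length(res$dropped_fit))
    warning("dropping column(s) ",
            paste0("'", nms[res$dropped_fit], "'", collapse = ", "),
            " (non-identifiable or divergent fit)", call. = FALSE)
  if (res$empty)
    return(list(variables = character(0), beta = numeric(0),
                se = numeric(0), p = numeric(0), empty = TRUE))
  sel <- nms[res$selected + 1L]
  list(variables = sel, beta = setNames(as.numeric(res$beta), sel),
       se = setNames(as.numeric(res$se), sel),
       p = setNames(pmax(as.numeric(res$p), 1e-300), sel), empty = FALSE)
}

#' Build a prognostic signature by backward elimination
#'
#' Starting from all frequency-filtered variables (plus any mandatory
#' covariates, which are never eligible for removal), iteratively fits the
#' multivariate Cox model and removes the eligible variable with the largest
#' Wald p while that p exceeds \code{pRemove}, refitting after each removal.
#' Stops when every eligible p is at most \code{pRemove} or no eligible
#' variable remains. When two variables tie at the maximal p, the
#' lexicographically last name is removed, so builds are deterministic.
#'
#' Subjects with a missing entry in any candidate column are excluded
#' listwise. Constant or duplicated columns are dropped with a warning
#' before fitting; if every variable is eliminated an empty model is
#' returned with \code{emptyModel = TRUE}.
#'
#' @param coded a [CodedMatrix-class] of candidate variables.
#' @param surv a [SurvivalData-class] row-aligned with \code{coded}.
#' @param pRemove stay threshold on the Wald p (default 0.10).
#' @param mandatory data.frame or named matrix of covariate columns (e.g.
#'   stage) forced into the model and never removed; NULL for none.
#' @param entrySet "all" (default) offers every filtered variable;
#'   "univariate" restricts candidates to variables significant in a
#'   univariate screen at \code{entryAlpha}.
#' @param entryAlpha significance level for the univariate-gated entry set.
#' @param ties tie-handling method.
#' @return a [PrognosticModel-class].
#' @export
backwardEliminate <- function(coded, surv, pRemove = 0.10, mandatory = NULL,
                              entrySet = c("all", "univariate"),
                              entryAlpha = 0.05,
                              ties = c("efron", "breslow")) {
  entrySet <- match.arg(entrySet)
  ties <- match.arg(ties)
  stopifnot(is(coded, "CodedMatrix"), is(surv, "SurvivalData"))
  if (pRemove <= 0 || pRemove >= 1) stop("'pRemove' must be in (0, 1)")
  V <- coded@values
  if (entrySet == "univariate") {
    rep <- univariateScreen(coded, surv, alpha = entryAlpha, ties = ties)
    keep <- rep@table$variable[rep@table$significant]
    V <- V[, intersect(colnames(V), keep), drop = FALSE]
  }
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
  X <- X[use, , drop = FALSE]
  keepNames <- .screen_columns(X, protect = if (is.null(M)) character(0)
                                            else colnames(M))
  eligible <- eligible[match(keepNames, colnames(X))]
  X <- X[, keepNames, drop = FALSE]
  res <- .backward_core(X, surv@time[use], surv@event[use], eligible,
                        pRemove, efron = ties == "efron")
  droppedForFit <- setdiff(colnames(cbind(V, M)), keepNames)
  if (res$empty)
    return(new("PrognosticModel", variables = character(0),
               coefficients = numeric(0), se = numeric(0), p = numeric(0),
               hr = numeric(0), ciLower = numeric(0), ciUpper = numeric(0),
               emptyModel = TRUE, droppedForFit = droppedForFit,
               nUsed = sum(use)))
  new("PrognosticModel", variables = res$variables,
      coefficients = as.numeric(res$beta), se = as.numeric(res$se),
      p = as.numeric(res$p), hr = exp(as.numeric(res$beta)),
      ciLower = exp(as.numeric(res$beta) - 1.96 * as.numeric(res$se)),
      ciUpper = exp(as.numeric(res$beta) + 1.96 * as.numeric(res$se)),
      emptyModel = FALSE, droppedForFit = droppedForFit,
      nUsed = sum(use))
}

#' Prognostic index of a subject profile
#'
#' The coefficient-weighted sum (Cox linear predictor) of the model's
#' variables: PI = sum of beta_i x_i. A high PI corresponds to a high
#' predicted hazard. An empty model gives PI = 0 for every subject.
#'
#' @param model a [PrognosticModel-class].
#' @param x named numeric vector, matrix or data.frame providing every model
#'   variable (extra entries ignored).
#' @return numeric prognostic index (one per row of \code{x}).
#' @examples
#' ## a subject carrying only the two adverse markers of a five-marker model
#' ## scores PI = log(1.948) + log(1.484)
#' @export
prognosticIndex <- function(model, x) {
  stopifnot(is(model, "PrognosticModel"))
  if (model@emptyModel) {
    n <- if (is.null(dim(x))) 1L else nrow(x)
    return(rep(0, n))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing_vars <- setdiff(model@variables, colnames(x))
  if (length(missing_vars))
    stop("profile lacks model variable(s): ",
         paste(missing_vars, collapse = ", "))
  xm <- x[, model@variables, drop = FALSE]
  if (anyNA(xm))
    stop("missing entries for model variables; impute or exclude first")
  as.numeric(xm %*% model@coefficients)
}

#' Serialize a univariate report or model as a results table
#'
#' Reproduces the standard reporting layout: variable, HR, 95\% CI, p.
#'
#' @param x a [UnivariateReport-class] or [PrognosticModel-class].
#' @param onlySignificant for reports, keep flagged rows only.
#' @return data.frame.
#' @export
resultsTable <- function(x, onlySignificant = FALSE) {
  if (is(x, "UnivariateReport")) {
    t <- x@table
    if (onlySignificant) t <- t[t$significant & !t$fitFailed, , drop = FALSE]
    data.frame(variable = t$variable, HR = t$hr,
               CI95 = sprintf("[%.3f, %.3f]", t$ciLower, t$ciUpper),
               p = t$p, stringsAsFactors = FALSE)
  } else if (is(x, "PrognosticModel")) {
    data.frame(variable = x@variables, HR = x@hr,
               CI95 = sprintf("[%.3f, %.3f]", x@ciLower, x@ciUpper),
               p = x@p, stringsAsFactors = FALSE)
  } else stop("unsupported object")
}
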