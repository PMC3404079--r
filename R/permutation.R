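#' @include AllClasses.R cv-risk.R
NULL

## Draw the B permutation vectors up front from one seed. Because every
## replicate's permutation is fixed before any work starts, processing them
## serially or in parallel gives bit-identical results.
.draw_permutations <- function(n, B, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ## a reserve pool allows failed replicates to be re-drawn deterministically
  lapply(seq_len(2L * B), function(i) sample.int(n))
}

.run_replicates <- function(perms, B, fun, parallel = FALSE, cores = 2L) {
  ## evaluate fun(perm) over the pre-drawn permutations; a replicate that
  ## fails wholesale is flagged and replaced by the next reserve draw
  run1 <- function(pm) tryCatch(fun(pm), error = function(e) NA_real_)
  vals <- if (parallel && .Platform$OS.type != "windows") {
    unlist(parallel::mclapply(perms, run1, mc.cores = cores))
  } else {
    vapply(perms, run1, numeric(1))
  }
  okVals <- vals[!is.na(vals)]
  failed <- sum(is.na(vals[seq_len(min(B, length(vals)))]))
  if (length(okVals) < B)
    stop("too many permutation replicates failed (",
         sum(is.na(vals)), " of ", length(vals), ")")
  if (failed > 0)
    message(failed, " permutation replicate(s) failed and were re-drawn")
  okVals[seq_len(B)]
}

#' Permutation significance of the cross-validated log-rank statistic
#'
#' The observed statistic is LR_d from [loocvRiskClassify()] on the real
#' data. For each of B permutations the (time, event) pairs are shuffled
#' jointly among subjects — genotypes stay put — and the entire leave-one-out
#' procedure, per-fold feature selection included, is rerun to produce a
#' null LR value. The permutation significance level is the add-one tail
#' fraction (1 + #\{null >= observed\}) / (1 + B).
#'
#' @param coded a [CodedMatrix-class].
#' @param surv a [SurvivalData-class].
#' @param mandatory optional covariate column(s) forced into every model.
#' @param pRemove backward-elimination stay threshold.
#' @param B number of permutations (default 500).
#' @param seed seed for the permutation stream.
#' @param ties tie-handling method.
#' @param parallel process replicates with parallel::mclapply; results are
#'   identical to a serial run because all permutations are drawn up front.
#' @param cores worker count when \code{parallel}.
#' @return a [PermutationResult-class].
#' @export
permutationSignificance <- function(coded, surv, mandatory = NULL,
                                    pRemove = 0.10, B = 500, seed = 1L,
                                    ties = c("efron", "breslow"),
                                    parallel = FALSE, cores = 2L) {
  ties <- match.arg(ties)
  if (B < 1) stop("B must be at least 1")
  efron <- ties == "efron"
  prep <- .cv_prepare(coded, surv, mandatory)
  n <- nrow(prep$X)
  time <- surv@time[prep$use]; event <- surv@event[prep$use]

  ## a cross-validated split that puts every subject in one group (all fold
  ## models empty, prognostic indices tied at the median) carries no
  ## discriminating information: its log-rank contribution is zero.
  ## The transposed design and lexicographic ranks are permutation-invariant,
  ## so they are computed once for all replicates.
  Xt <- t(prep$X)
  lex <- as.integer(rank(colnames(prep$X)))
  cvStat <- function(tm, ev) {
    ev <- as.integer(ev)
    res <- .cox_loocv_cpp(Xt, tm, ev, as.integer(order(tm) - 1L),
                          prep$eligible, lex, pRemove, efron,
                          1e-8, 40L, 12, FALSE)
    high <- as.logical(res$high)
    if (all(high) || !any(high)) return(0)
    .log_rank_raw(tm, ev, high)$statistic
  }
  observed <- cvStat(time, event)
  perms <- .draw_permutations(n, B, seed)
  nulls <- .run_replicates(perms, B,
                           function(pm) cvStat(time[pm], event[pm]),
                           parallel = parallel, cores = cores)
  p <- (1 + sum(nulls >= observed)) / (1 + B)
  new("PermutationResult", observed = observed, nullStatistics = nulls,
      pValue = p, B = as.integer(B), seed = as.integer(seed),
      statistic = "cross-validated log-rank LR_d (survival shuffle)")
}

#' Added value of genotypes beyond a clinical covariate
#'
#' Tests whether the genotype data improve risk discrimination beyond the
#' covariate (stage). The statistic is the difference between the
#' cross-validated log-rank statistic of the combined model (genotypes with
#' the covariate mandatory in every fold) and that of the covariate-only
#' model (the covariate's Cox coefficient alone drives the prognostic
#' index; no feature selection). The null distribution permutes whole
#' genotype rows among subjects while the (time, event, covariate) triples
#' stay intact, and reruns the combined cross-validation per replicate; the
#' covariate-only statistic is unaffected by genotype permutation, so its
#' value is shared across replicates.
#'
#' @param coded a [CodedMatrix-class].
#' @param covariate numeric covariate vector (e.g. stage), row-aligned.
#' @param surv a [SurvivalData-class].
#' @param pRemove backward-elimination stay threshold.
#' @param B number of permutations (default 500).
#' @param seed seed for the permutation stream.
#' @param ties tie-handling method.
#' @param parallel,cores as in [permutationSignificance()].
#' @return a [PermutationResult-class]; \code{observed} is the LR difference.
#' @export
compareWithCovariate <- function(coded, covariate, surv, pRemove = 0.10,
                                 B = 500, seed = 1L,
                                 ties = c("efron", "breslow"),
                                 parallel = FALSE, cores = 2L) {
  ties <- match.arg(ties)
  if (B < 1) stop("B must be at least 1")
  efron <- ties == "efron"
  covariate <- as.numeric(covariate)
  M <- cbind(stage = covariate)
  prep <- .cv_prepare(coded, surv, M)
  n <- nrow(prep$X)
  time <- surv@time[prep$use]; event <- surv@event[prep$use]
  stg <- covariate[prep$use]

  ## degenerate single-group splits contribute statistic 0 (no
  ## discrimination); see permutationSignificance. The survival ordering is
  ## fixed under genotype permutation, so it is computed once.
  lex <- as.integer(rank(colnames(prep$X)))
  ordFixed <- as.integer(order(time) - 1L)
  eventInt <- as.integer(event)
  combinedStat <- function(Xt) {
    res <- .cox_loocv_cpp(Xt, time, eventInt, ordFixed, prep$eligible, lex,
                          pRemove, efron, 1e-8, 40L, 12, FALSE)
    high <- as.logical(res$high)
    if (all(high) || !any(high)) return(0)
    .log_rank_raw(time, eventInt, high)$statistic
  }
  ## covariate-only model: stage always in, no selection
  covStat <- local({
    Xc <- cbind(stage = stg)
    res <- .loocv_core(Xc, time, event, FALSE, pRemove, efron = efron)
    if (all(res$high) || !any(res$high)) 0
    else .log_rank_raw(time, event, res$high)$statistic
  })
  XtObs <- t(prep$X)
  observed <- combinedStat(XtObs) - covStat

  genoRows <- which(prep$eligible)
  marginalKM <- kaplanMeier(survivalData(time, event))
  perms <- .draw_permutations(n, B, seed)
  nulls <- .run_replicates(perms, B, function(pm) {
    Xp <- XtObs
    Xp[genoRows, ] <- XtObs[genoRows, pm, drop = FALSE]
    ## survival untouched by construction: the cohort's marginal KM curve is
    ## identical in every replicate
    stopifnot(identical(kaplanMeier(survivalData(time, event))@surv,
                        marginalKM@surv))
    combinedStat(Xp) - covStat
  }, parallel = parallel, cores = cores)
  p <- (1 + sum(nulls >= observed)) / (1 + B)
  new("PermutationResult", observed = observed, nullStatistics = nulls,
      pValue = p, B = as.integer(B), seed = as.integer(seed),
      statistic = "LR_d(combined) - LR_d(covariate) (genotype-row shuffle)")
}
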