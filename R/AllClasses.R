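#' @import methods
#' @importFrom stats median pchisq pnorm qnorm rexp runif setNames quantile
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib survSigCV, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Locus and cohort configuration
## ---------------------------------------------------------------------------

#' LocusSpec: population description of one typed locus
#'
#' A locus is described by its label, its kind (a multi-allelic locus typed as
#' two allele calls, a biallelic SNP typed as a diplotype, or a microsatellite
#' typed as two fragment lengths) and a population allele-frequency vector
#' used for Hardy-Weinberg sampling.
#'
#' @slot name single locus label, e.g. \code{"DRB1"} or \code{"CT60"}.
#' @slot kind one of \code{"multiallelic"}, \code{"snp"},
#'   \code{"microsatellite"}.
#' @slot alleleLabels character vector of allele names, unique within locus.
#' @slot alleleFreqs numeric probability vector aligned with
#'   \code{alleleLabels}; non-negative, sums to 1 (tolerance 1e-9).
#' @exportClass LocusSpec
setClass("LocusSpec",
  representation(name = "character", kind = "character",
                 alleleLabels = "character", alleleFreqs = "numeric"))

setValidity("LocusSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("multiallelic", "snp", "microsatellite"))
    msg <- c(msg, "'kind' must be one of multiallelic/snp/microsatellite")
  if (length(object@alleleLabels) != length(object@alleleFreqs))
    msg <- c(msg, "allele labels and frequencies differ in length")
  if (anyDuplicated(object@alleleLabels))
    msg <- c(msg, "allele labels must be unique within a locus")
  if (any(object@alleleFreqs < 0))
    msg <- c(msg, "allele frequencies must be non-negative")
  if (abs(sum(object@alleleFreqs) - 1) > 1e-9)
    msg <- c(msg, "allele frequencies must sum to 1 (tolerance 1e-9)")
  if (length(object@kind) == 1L &&
      object@kind %in% c("snp", "microsatellite") &&
      length(object@alleleLabels) < 2L)
    msg <- c(msg, "snp/microsatellite loci need at least 2 alleles")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: full description of a synthetic cohort
#'
#' Bundles the locus panel, planted log-hazard effects, the baseline
#' event-time model, censoring, the stage covariate and the master seed.
#' Construct with [cohortConfig()] or [makeScenario()].
#'
#' @slot nSubjects integer cohort size (>= 2).
#' @slot loci list of [LocusSpec-class] objects.
#' @slot effects named numeric vector of log hazard ratios; names must
#'   resolve to coded variable names produced by the coding rules.
#' @slot baseline list with \code{dist} ("exponential" or "weibull") and its
#'   strictly positive parameters (\code{rate}, or \code{shape}/\code{scale}),
#'   months scale, for the death process.
#' @slot relapseRate strictly positive exponential rate of the additional
#'   relapse process sharing the same linear predictor; relapse-free survival
#'   is the minimum of the death and relapse times, so RFS <= OS by
#'   construction.
#' @slot censoring list with \code{horizon} (administrative cut-off, months,
#'   > 0, may be \code{Inf}) and \code{dropoutMax} (upper bound of an
#'   independent uniform dropout time; \code{Inf} disables dropout).
#' @slot stagePrevalence probability a subject is high stage.
#' @slot stageLogHazard log hazard ratio of high stage.
#' @slot missingRate probability an individual allele call is missing at
#'   random (default 0).
#' @slot seed integer master seed; every operation derives its own stream.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(nSubjects = "integer", loci = "list", effects = "numeric",
                 baseline = "list", relapseRate = "numeric",
                 censoring = "list", stagePrevalence = "numeric",
                 stageLogHazard = "numeric", missingRate = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (!all(vapply(object@loci, is, logical(1), "LocusSpec")))
    msg <- c(msg, "'loci' must be a list of LocusSpec objects")
  if (length(object@effects) && is.null(names(object@effects)))
    msg <- c(msg, "'effects' must be a named numeric vector")
  b <- object@baseline
  if (is.null(b$dist) || !b$dist %in% c("exponential", "weibull")) {
    msg <- c(msg, "baseline$dist must be 'exponential' or 'weibull'")
  } else if (b$dist == "exponential") {
    if (is.null(b$rate) || b$rate <= 0)
      msg <- c(msg, "baseline$rate must be > 0")
  } else {
    if (is.null(b$shape) || is.null(b$scale) || b$shape <= 0 || b$scale <= 0)
      msg <- c(msg, "baseline shape/scale must be > 0")
  }
  if (object@relapseRate <= 0) msg <- c(msg, "relapseRate must be > 0")
  if (is.null(object@censoring$horizon) || object@censoring$horizon <= 0)
    msg <- c(msg, "censoring$horizon must be > 0 (Inf allowed)")
  if (object@stagePrevalence < 0 || object@stagePrevalence > 1)
    msg <- c(msg, "stagePrevalence must be in [0,1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0,1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' GenotypeTable: raw per-subject allele calls
#'
#' Holds, for each typed locus, the two allele calls of every subject
#' (identical calls denote homozygosity; \code{NA} denotes a missing call).
#'
#' @slot subjectIds unique subject labels.
#' @slot calls named list; one n x 2 character matrix per locus.
#' @slot locusKinds named character vector mapping locus name to its kind.
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(subjectIds = "character", calls = "list",
                 locusKinds = "character"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  n <- length(object@subjectIds)
  if (n < 1L) msg <- c(msg, "at least one subject required")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subject ids must be unique")
  if (is.null(names(object@calls)) || anyDuplicated(names(object@calls)))
    msg <- c(msg, "'calls' must be uniquely named by locus")
  for (nm in names(object@calls)) {
    m <- object@calls[[nm]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) != n)
      msg <- c(msg, sprintf("locus '%s' must be an n x 2 matrix", nm))
  }
  if (!setequal(names(object@calls), names(object@locusKinds)))
    msg <- c(msg, "locusKinds must name exactly the loci in 'calls'")
  if (length(msg)) msg else TRUE
})

#' CodedMatrix: subjects x binary design variables
#'
#' The binary design matrix produced by [codeAlleles()]: one carrier-presence
#' column per observed allele (1 if the subject carries at least one copy),
#' one homozygosity column per allele (1 iff both calls equal that allele),
#' and genotype-level columns for SNP diplotypes. Entries are 0, 1 or
#' \code{NA} (missing call). [filterByFrequency()] drops low-frequency
#' columns and records them.
#'
#' @slot values numeric matrix in \{0,1,NA\}; rownames are subject ids,
#'   colnames are variable names.
#' @slot carrierFreq per-column carrier frequency (mean over subjects with a
#'   non-missing entry).
#' @slot parentVariable named character; for a homozygosity column, the name
#'   of its parent presence column (\code{NA} otherwise).
#' @slot dropped variable names removed by the frequency filter.
#' @slot threshold the carrier-frequency threshold applied (\code{NA} before
#'   filtering).
#' @exportClass CodedMatrix
setClass("CodedMatrix",
  representation(values = "matrix", carrierFreq = "numeric",
                 parentVariable = "character", dropped = "character",
                 threshold = "numeric"))

setValidity("CodedMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have subject rownames and variable colnames")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "variable names must be unique")
  vv <- v[!is.na(v)]
  if (length(vv) && !all(vv %in% c(0, 1)))
    msg <- c(msg, "entries must be 0, 1 or NA")
  if (length(object@carrierFreq) != ncol(v))
    msg <- c(msg, "carrierFreq must have one entry per column")
  ## a homozygosity indicator implies carriage of its parent allele
  pv <- object@parentVariable
  for (nm in names(pv)[!is.na(pv)]) {
    if (pv[[nm]] %in% colnames(v)) {
      hom <- v[, nm]; par <- v[, pv[[nm]]]
      bad <- !is.na(hom) & !is.na(par) & hom == 1 & par != 1
      if (any(bad))
        msg <- c(msg, sprintf("homozygosity column '%s' set without parent", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SurvivalData: censored follow-up for one endpoint
#'
#' @slot subjectIds subject labels aligned with time/event.
#' @slot time non-negative follow-up time in months.
#' @slot event 1 = event observed, 0 = censored.
#' @slot endpoint label, e.g. \code{"OS"} or \code{"RFS"}.
#' @exportClass SurvivalData
setClass("SurvivalData",
  representation(subjectIds = "character", time = "numeric",
                 event = "integer", endpoint = "character"))

setValidity("SurvivalData", function(object) {
  msg <- character()
  if (length(object@time) < 1L) msg <- c(msg, "at least one record required")
  if (length(object@time) != length(object@event) ||
      length(object@time) != length(object@subjectIds))
    msg <- c(msg, "subjectIds, time and event must be aligned")
  if (any(!is.finite(object@time)) || any(object@time < 0))
    msg <- c(msg, "times must be finite and >= 0")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot time distinct observed event times, ascending.
#' @slot surv survival estimate S(t) at each event time; non-increasing in
#'   [0,1].
#' @slot nRisk number at risk just before each event time.
#' @slot nEvent number of events at each event time.
#' @slot n number of subjects.
#' @exportClass KMCurve
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", nRisk = "numeric",
                 nEvent = "numeric", n = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly ascending")
  s <- object@surv
  if (length(s)) {
    if (any(s < -1e-12) || any(s > 1 + 1e-12)) msg <- c(msg, "S must lie in [0,1]")
    if (any(diff(s) > 1e-12)) msg <- c(msg, "S must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' LogRankResult: two-sample log-rank test
#'
#' @slot statistic chi-square statistic (1 df).
#' @slot pValue asymptotic upper tail probability.
#' @slot observed per-group observed event counts.
#' @slot expected per-group expected event counts.
#' @slot n per-group sizes.
#' @exportClass LogRankResult
setClass("LogRankResult",
  representation(statistic = "numeric", pValue = "numeric",
                 observed = "numeric", expected = "numeric", n = "integer"))

setValidity("LogRankResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' CoxFit: proportional-hazards fit with Wald inference
#'
#' @slot coefficients named log hazard ratios.
#' @slot se standard errors from the observed information.
#' @slot z Wald z statistics.
#' @slot p two-sided Wald p values.
#' @slot hr exp(beta).
#' @slot ciLower,ciUpper 95\% Wald interval exp(beta -/+ 1.96 se).
#' @slot logLik maximized log partial likelihood.
#' @slot logLikNull log partial likelihood at beta = 0.
#' @slot iterations Newton iterations used.
#' @slot converged logical.
#' @slot ties \code{"efron"} or \code{"breslow"}.
#' @slot n,nEvent subjects and events used.
#' @exportClass CoxFit
setClass("CoxFit",
  representation(coefficients = "numeric", se = "numeric", z = "numeric",
                 p = "numeric", hr = "numeric", ciLower = "numeric",
                 ciUpper = "numeric", logLik = "numeric",
                 logLikNull = "numeric", iterations = "integer",
                 converged = "logical", ties = "character", n = "integer",
                 nEvent = "integer"))

setValidity("CoxFit", function(object) {
  msg <- character()
  ok <- is.finite(object@hr)
  if (any(object@hr[ok] <= 0)) msg <- c(msg, "hazard ratios must be > 0")
  if (any(object@ciLower[ok] > object@hr[ok] + 1e-8) ||
      any(object@ciUpper[ok] < object@hr[ok] - 1e-8))
    msg <- c(msg, "confidence bounds must bracket the hazard ratio")
  pp <- object@p[is.finite(object@p)]
  if (any(pp <= 0) || any(pp > 1)) msg <- c(msg, "Wald p must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Modelling results
## ---------------------------------------------------------------------------

#' UnivariateReport: per-variable Cox screening results
#'
#' @slot table data.frame with columns variable, p, hr, ciLower, ciUpper,
#'   nUsed, significant, fitFailed; sorted by p.
#' @slot alpha significance level used for flagging.
#' @exportClass UnivariateReport
setClass("UnivariateReport",
  representation(table = "data.frame", alpha = "numeric"))

#' PrognosticModel: backward-elimination Cox signature
#'
#' @slot variables selected variable names (may be empty).
#' @slot coefficients,se,p,hr,ciLower,ciUpper aligned with variables.
#' @slot emptyModel TRUE when every candidate was eliminated.
#' @slot droppedForFit columns dropped before fitting (constant/duplicated).
#' @slot nUsed subjects entering the (listwise-complete) fit.
#' @exportClass PrognosticModel
setClass("PrognosticModel",
  representation(variables = "character", coefficients = "numeric",
                 se = "numeric", p = "numeric", hr = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 emptyModel = "logical", droppedForFit = "character",
                 nUsed = "integer"))

setValidity("PrognosticModel", function(object) {
  k <- length(object@variables)
  if (length(object@coefficients) != k)
    return("coefficients must align with variables")
  if (k == 0L && !object@emptyModel)
    return("a model with no variables must set emptyModel")
  TRUE
})

#' CvRiskResult: leave-one-out cross-validated risk classification
#'
#' @slot subjectIds subject labels.
#' @slot pi cross-validated prognostic index of each held-out subject.
#' @slot riskGroup factor with levels \code{low}, \code{high}.
#' @slot foldModels list of per-fold selected variables and coefficients.
#' @slot kmLow,kmHigh cross-validated Kaplan-Meier curves per risk group.
#' @slot logRank the cross-validated log-rank statistic LR_d and p.
#' @slot groupSizes,eventCounts named (low/high) totals.
#' @slot medianSurvival named KM median per group (NA if not reached).
#' @slot endpoint evaluation endpoint label.
#' @exportClass CvRiskResult
setClass("CvRiskResult",
  representation(subjectIds = "character", pi = "numeric",
                 riskGroup = "factor", foldModels = "list",
                 kmLow = "KMCurve", kmHigh = "KMCurve",
                 logRank = "LogRankResult", groupSizes = "integer",
                 eventCounts = "integer", medianSurvival = "numeric",
                 endpoint = "character"))

setValidity("CvRiskResult", function(object) {
  msg <- character()
  n <- length(object@subjectIds)
  if (length(object@pi) != n || length(object@riskGroup) != n)
    msg <- c(msg, "pi and riskGroup must align with subjects")
  if (anyNA(object@riskGroup))
    msg <- c(msg, "every subject must be assigned a risk group")
  if (sum(object@groupSizes) != n)
    msg <- c(msg, "group sizes must sum to n")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: permutation null for an observed statistic
#'
#' @slot observed observed statistic.
#' @slot nullStatistics vector of B null statistics.
#' @slot pValue add-one permutation p, (1 + #\{null >= observed\}) / (1 + B).
#' @slot B number of permutations.
#' @slot seed seed used for the permutation stream.
#' @slot statistic label of the statistic.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(observed = "numeric", nullStatistics = "numeric",
                 pValue = "numeric", B = "integer", seed = "integer",
                 statistic = "character"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  B <- object@B
  if (length(object@nullStatistics) != B)
    msg <- c(msg, "null vector length must equal B")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p must lie in (0,1]")
  if (object@pValue < 1 / (B + 1) - 1e-12)
    msg <- c(msg, "p cannot fall below 1/(B+1)")
  if (length(msg)) msg else TRUE
})

#' TimeROC: time-dependent ROC curve at one horizon
#'
#' Cumulative-case / dynamic-control ROC of a continuous marker for the
#' outcome "event by time t" under censoring, estimated from Kaplan-Meier
#' components.
#'
#' @slot time evaluation horizon t (months).
#' @slot thresholds threshold grid (midpoints between unique marker values,
#'   with -Inf/Inf anchors), descending so the curve runs (0,0) -> (1,1).
#' @slot tp,fp true/false positive rates per threshold, clipped to [0,1].
#' @slot auc trapezoidal area under the (fp, tp) curve.
#' @slot corrected whether the monotone (cumulative-maximum) correction was
#'   applied.
#' @exportClass TimeROC
setClass("TimeROC",
  representation(time = "numeric", thresholds = "numeric", tp = "numeric",
                 fp = "numeric", auc = "numeric", corrected = "logical"))

setValidity("TimeROC", function(object) {
  msg <- character()
  if (any(object@tp < -1e-9) || any(object@tp > 1 + 1e-9) ||
      any(object@fp < -1e-9) || any(object@fp > 1 + 1e-9))
    msg <- c(msg, "TP and FP must lie in [0,1]")
  if (object@auc < -1e-9 || object@auc > 1 + 1e-9)
    msg <- c(msg, "AUC must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' AnalysisReport: results of a full pipeline run
#'
#' @slot univariateOS,univariateRFS univariate screening reports.
#' @slot modelOS,modelCombined full-data signatures (without / with the
#'   mandatory stage covariate).
#' @slot loocvOS,loocvCombined cross-validated risk classifications on OS.
#' @slot permutationOS,permutationCombined survival-shuffle permutation
#'   tests of the cross-validated log-rank statistic.
#' @slot covariateComparison genotype-permutation test of added value beyond
#'   stage.
#' @slot crossEndpointOS,crossEndpointCombined OS-built models validated on
#'   RFS.
#' @slot aucTimeline data.frame of (model, time, auc).
#' @slot config the run configuration used.
#' @exportClass AnalysisReport
setClass("AnalysisReport",
  representation(univariateOS = "UnivariateReport",
                 univariateRFS = "UnivariateReport",
                 modelOS = "PrognosticModel",
                 modelCombined = "PrognosticModel",
                 loocvOS = "CvRiskResult",
                 loocvCombined = "CvRiskResult",
                 permutationOS = "PermutationResult",
                 permutationCombined = "PermutationResult",
                 covariateComparison = "PermutationResult",
                 crossEndpointOS = "CvRiskResult",
                 crossEndpointCombined = "CvRiskResult",
                 aucTimeline = "data.frame",
                 config = "list"))
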