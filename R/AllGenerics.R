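#' @include AllClasses.R
NULL

#' Subject identifiers of a container
#' @param x a package data object.
#' @return character vector of subject ids.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Variable names of a coded matrix or model
#' @param x a [CodedMatrix-class] or [PrognosticModel-class].
#' @return character vector of variable names.
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' Per-variable carrier frequencies
#' @param x a [CodedMatrix-class].
#' @return named numeric vector.
#' @export
setGeneric("carrierFrequencies",
           function(x) standardGeneric("carrierFrequencies"))

#' Binary design values of a coded matrix
#' @param x a [CodedMatrix-class].
#' @return numeric matrix in \{0,1,NA\}.
#' @export
setGeneric("codedValues", function(x) standardGeneric("codedValues"))

#' Follow-up times
#' @param x a [SurvivalData-class].
#' @return numeric vector, months.
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' Event indicators (1 = event, 0 = censored)
#' @param x a [SurvivalData-class].
#' @return integer vector.
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' Cross-validated risk-group labels
#' @param x a [CvRiskResult-class].
#' @return factor with levels low/high.
#' @export
setGeneric("riskGroups", function(x) standardGeneric("riskGroups"))

#' Cross-validated prognostic indices
#' @param x a [CvRiskResult-class].
#' @return numeric vector aligned with subjects.
#' @export
setGeneric("prognosticIndices",
           function(x) standardGeneric("prognosticIndices"))

## ---------------------------------------------------------------------------
## Accessor methods
## ---------------------------------------------------------------------------

#' @describeIn GenotypeTable subject ids.
#' @param x object.
#' @export
setMethod("subjectIds", "GenotypeTable", function(x) x@subjectIds)

#' @describeIn CodedMatrix subject ids.
#' @param x object.
#' @export
setMethod("subjectIds", "CodedMatrix", function(x) rownames(x@values))

#' @describeIn SurvivalData subject ids.
#' @param x object.
#' @export
setMethod("subjectIds", "SurvivalData", function(x) x@subjectIds)

#' @describeIn CvRiskResult subject ids.
#' @param x object.
#' @export
setMethod("subjectIds", "CvRiskResult", function(x) x@subjectIds)

#' @describeIn CodedMatrix variable names.
#' @export
setMethod("variableNames", "CodedMatrix", function(x) colnames(x@values))

#' @describeIn PrognosticModel selected variable names.
#' @export
setMethod("variableNames", "PrognosticModel", function(x) x@variables)

#' @describeIn CodedMatrix carrier frequencies.
#' @export
setMethod("carrierFrequencies", "CodedMatrix",
          function(x) setNames(x@carrierFreq, colnames(x@values)))

#' @describeIn CodedMatrix binary design values.
#' @export
setMethod("codedValues", "CodedMatrix", function(x) x@values)

#' @describeIn SurvivalData follow-up times.
#' @export
setMethod("survTime", "SurvivalData", function(x) x@time)

#' @describeIn SurvivalData event indicators.
#' @export
setMethod("survEvent", "SurvivalData", function(x) x@event)

#' @describeIn CvRiskResult risk-group labels.
#' @export
setMethod("riskGroups", "CvRiskResult", function(x) x@riskGroup)

#' @describeIn CvRiskResult cross-validated prognostic indices.
#' @export
setMethod("prognosticIndices", "CvRiskResult",
          function(x) setNames(x@pi, x@subjectIds))

#' @describeIn CoxFit estimated log hazard ratios.
#' @param object a fit or model.
#' @param ... ignored.
#' @export
setMethod("coef", "CoxFit", function(object, ...) object@coefficients)

#' @describeIn PrognosticModel estimated log hazard ratios of the selected
#'   variables.
#' @param object a fit or model.
#' @param ... ignored.
#' @export
setMethod("coef", "PrognosticModel", function(object, ...)
  setNames(object@coefficients, object@variables))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "LocusSpec", function(object) {
  cat(sprintf("LocusSpec '%s' (%s): %d alleles\n", object@name, object@kind,
              length(object@alleleLabels)))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d subjects, %d loci, %d planted effects, seed %d\n",
              object@nSubjects, length(object@loci), length(object@effects),
              object@seed))
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d subjects x %d loci (%s)\n",
              length(object@subjectIds), length(object@calls),
              paste(names(object@calls), collapse = ", ")))
})

setMethod("show", "CodedMatrix", function(object) {
  cat(sprintf("CodedMatrix: %d subjects x %d binary variables\n",
              nrow(object@values), ncol(object@values)))
  if (!is.na(object@threshold))
    cat(sprintf("  carrier-frequency filter >= %.3f (%d variables dropped)\n",
                object@threshold, length(object@dropped)))
})

setMethod("show", "SurvivalData", function(object) {
  cat(sprintf("SurvivalData [%s]: %d subjects, %d events, median follow-up %.1f months\n",
              object@endpoint, length(object@time), sum(object@event),
              stats::median(object@time)))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d subjects, %d distinct event times\n",
              object@n, length(object@time)))
})

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank: chi-square = %.4f (1 df), p = %.4g\n",
              object@statistic, object@pValue))
})

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit (%s ties): %d subjects, %d events%s\n", object@ties,
              object@n, object@nEvent,
              if (object@converged) "" else " [NOT CONVERGED]"))
  df <- data.frame(HR = round(object@hr, 3),
                   `95% CI` = sprintf("[%.3f, %.3f]", object@ciLower,
                                      object@ciUpper),
                   p = signif(object@p, 3), check.names = FALSE)
  rownames(df) <- names(object@coefficients)
  print(df)
})

setMethod("show", "UnivariateReport", function(object) {
  cat(sprintf("UnivariateReport: %d variables screened, %d significant at alpha = %.2g\n",
              nrow(object@table), sum(object@table$significant, na.rm = TRUE),
              object@alpha))
  print(head(object@table, 10))
  if (nrow(object@table) > 10) cat("  ...\n")
})

setMethod("show", "PrognosticModel", function(object) {
  if (object@emptyModel) {
    cat("PrognosticModel: empty (all variables eliminated)\n")
  } else {
    cat(sprintf("PrognosticModel: %d variables\n", length(object@variables)))
    df <- data.frame(HR = round(object@hr, 3),
                     `95% CI` = sprintf("[%.3f, %.3f]", object@ciLower,
                                        object@ciUpper),
                     p = signif(object@p, 3), check.names = FALSE)
    rownames(df) <- object@variables
    print(df)
  }
})

setMethod("show", "CvRiskResult", function(object) {
  cat(sprintf("CvRiskResult [%s]: %d low risk (%d events), %d high risk (%d events)\n",
              object@endpoint,
              object@groupSizes[["low"]], object@eventCounts[["low"]],
              object@groupSizes[["high"]], object@eventCounts[["high"]]))
  med <- function(g) {
    m <- object@medianSurvival[[g]]
    if (is.na(m)) "not reached" else sprintf("%.1f months", m)
  }
  cat(sprintf("  median %s: low %s, high %s\n", object@endpoint,
              med("low"), med("high")))
  cat(sprintf("  cross-validated log-rank LR_d = %.4f, asymptotic p = %.4g\n",
              object@logRank@statistic, object@logRank@pValue))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult [%s]: observed = %.4f, B = %d, p = %.4g\n",
              object@statistic, object@observed, object@B, object@pValue))
})

setMethod("show", "TimeROC", function(object) {
  cat(sprintf("TimeROC at t = %.0f months: AUC = %.4f (%d thresholds%s)\n",
              object@time, object@auc, length(object@thresholds),
              if (object@corrected) ", monotone-corrected" else ""))
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n==============\n")
  cat("\n-- Univariate OS screen --\n"); show(object@univariateOS)
  cat("\n-- Signature (OS) --\n"); show(object@modelOS)
  cat("\n-- Signature (OS, stage mandatory) --\n"); show(object@modelCombined)
  cat("\n-- LOOCV risk groups (OS) --\n"); show(object@loocvOS)
  cat("\n-- LOOCV risk groups (OS, combined) --\n"); show(object@loocvCombined)
  cat("\n-- Permutation tests --\n")
  show(object@permutationOS); show(object@permutationCombined)
  show(object@covariateComparison)
  cat("\n-- Cross-endpoint validation (OS model on RFS) --\n")
  show(object@crossEndpointOS); show(object@crossEndpointCombined)
  cat("\n-- Time-dependent AUC --\n"); print(object@aucTimeline)
})
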