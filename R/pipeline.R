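#' @include AllClasses.R synthetic.R coding.R model-building.R cv-risk.R
#' @include permutation.R tdroc.R
NULL

#' Write a cohort as two delimited text tables
#'
#' Genotypes: one row per subject, columns \code{subject_id} then
#' \code{"<locus>:1"}, \code{"<locus>:2"} per locus; \code{NA} for missing
#' calls. Clinical: \code{subject_id, os_months, os_event, rfs_months,
#' rfs_event, stage}. Tab-delimited with headers.
#'
#' @param genotypes a [GenotypeTable-class].
#' @param os,rfs [SurvivalData-class] objects aligned with the genotypes.
#' @param stage integer stage vector.
#' @param genotypePath,clinicalPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeCohortTables <- function(genotypes, os, rfs, stage, genotypePath,
                              clinicalPath) {
  stopifnot(is(genotypes, "GenotypeTable"))
  gdf <- data.frame(subject_id = genotypes@subjectIds,
                    stringsAsFactors = FALSE)
  for (nm in names(genotypes@calls)) {
    gdf[[paste0(nm, ":1")]] <- genotypes@calls[[nm]][, 1]
    gdf[[paste0(nm, ":2")]] <- genotypes@calls[[nm]][, 2]
  }
  cdf <- data.frame(subject_id = os@subjectIds,
                    os_months = os@time, os_event = os@event,
                    rfs_months = rfs@time, rfs_event = rfs@event,
                    stage = as.integer(stage))
  write.table(gdf, genotypePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cdf, clinicalPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genotypePath, clinicalPath))
}

## classify a locus from its observed calls when no kind map is given
.infer_kind <- function(calls) {
  v <- unique(as.vector(calls[!is.na(calls)]))
  if (length(v) <= 2L && all(v %in% c("A", "C", "G", "T"))) "snp"
  else if (all(grepl("^[0-9]+$", v)) && all(as.numeric(v) > 100)) "microsatellite"
  else "multiallelic"
}

#' Read a cohort from delimited text tables
#'
#' Parses, validates and id-joins the genotype and clinical tables written
#' in the dialect of [writeCohortTables()]. The join follows the clinical
#' table's order; subjects present in only one table are an error.
#'
#' @param genotypePath,clinicalPath input file paths.
#' @param locusKinds optional named kind vector per locus; when NULL the
#'   kind is inferred (nucleotide biallelic calls = snp, numeric
#'   fragment-length calls = microsatellite, otherwise multiallelic).
#' @return list with \code{genotypes} ([GenotypeTable-class]), \code{os},
#'   \code{rfs} ([SurvivalData-class]) and \code{stage}.
#' @export
readCohortTables <- function(genotypePath, clinicalPath, locusKinds = NULL) {
  gdf <- read.delim(genotypePath, colClasses = "character",
                    check.names = FALSE)
  cdf <- read.delim(clinicalPath, check.names = FALSE)
  if (!"subject_id" %in% names(gdf) || !"subject_id" %in% names(cdf))
    stop("both tables must carry a 'subject_id' column")
  if (anyDuplicated(gdf$subject_id) || anyDuplicated(cdf$subject_id))
    stop("duplicate subject ids")
  orphanG <- setdiff(gdf$subject_id, cdf$subject_id)
  orphanC <- setdiff(cdf$subject_id, gdf$subject_id)
  if (length(orphanG) || length(orphanC))
    stop("subject id mismatch between tables; orphans: ",
         paste(c(orphanG, orphanC), collapse = ", "))
  need <- c("os_months", "os_event", "rfs_months", "rfs_event", "stage")
  missCol <- setdiff(need, names(cdf))
  if (length(missCol))
    stop("clinical table lacks column(s): ", paste(missCol, collapse = ", "))
  for (col in c("os_months", "rfs_months")) {
    v <- cdf[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("'", col, "' must be finite non-negative months")
  }
  for (col in c("os_event", "rfs_event")) {
    if (!all(cdf[[col]] %in% c(0, 1)))
      stop("'", col, "' must be 0 or 1")
  }
  if (any(cdf$rfs_months > cdf$os_months + 1e-9))
    warning("RFS time exceeds OS time for ",
            sum(cdf$rfs_months > cdf$os_months + 1e-9), " subject(s)",
            call. = FALSE)
  gdf <- gdf[match(cdf$subject_id, gdf$subject_id), , drop = FALSE]
  slotCols <- grep(":[12]$", names(gdf), value = TRUE)
  loci <- unique(sub(":[12]$", "", slotCols))
  calls <- lapply(loci, function(l) {
    m <- cbind(gdf[[paste0(l, ":1")]], gdf[[paste0(l, ":2")]])
    m[m == "NA" | m == ""] <- NA_character_
    m
  })
  names(calls) <- loci
  if (is.null(locusKinds))
    locusKinds <- vapply(calls, .infer_kind, character(1))
  gt <- genotypeTable(cdf$subject_id, calls, locusKinds[loci])
  list(genotypes = gt,
       os = survivalData(cdf$os_months, cdf$os_event, cdf$subject_id, "OS"),
       rfs = survivalData(cdf$rfs_months, cdf$rfs_event, cdf$subject_id,
                          "RFS"),
       stage = as.integer(cdf$stage))
}

#' Run configuration for the full analysis pipeline
#'
#' @param scenario synthetic scenario name (exclusive with the file paths).
#' @param genotypePath,clinicalPath input tables (exclusive with scenario).
#' @param nSubjects cohort size in synthetic mode.
#' @param loci locus panel for synthetic mode (default full panel).
#' @param freqThreshold carrier-frequency filter (default 0.10).
#' @param pRemove backward-elimination stay threshold (default 0.10).
#' @param entrySet candidate entry mode, "all" or "univariate".
#' @param excludeLoci loci whose coded variables are withheld from modelling
#'   (default the FOXP3 microsatellite, which is coded and screened but not
#'   offered to the signature).
#' @param B permutations per test (default 500).
#' @param aucTimes AUC evaluation horizons, months (default 60 and 84).
#' @param seed master seed.
#' @param ties tie-handling method.
#' @param parallel,cores permutation execution mode.
#' @return validated config list.
#' @export
runConfig <- function(scenario = NULL, genotypePath = NULL,
                      clinicalPath = NULL, nSubjects = 284, loci = NULL,
                      freqThreshold = 0.10, pRemove = 0.10,
                      entrySet = "all", excludeLoci = "FOXP3",
                      B = 500, aucTimes = c(60, 84), seed = 1L,
                      ties = "efron", parallel = FALSE, cores = 2L) {
  fileMode <- !is.null(genotypePath) || !is.null(clinicalPath)
  if (is.null(scenario) == !fileMode)
    stop("set exactly one of 'scenario' or the input file paths")
  if (fileMode && (is.null(genotypePath) || is.null(clinicalPath)))
    stop("both genotypePath and clinicalPath are required in file mode")
  if (freqThreshold <= 0 || freqThreshold >= 1)
    stop("freqThreshold must be in (0,1)")
  if (pRemove <= 0 || pRemove >= 1) stop("pRemove must be in (0,1)")
  if (B < 1) stop("B must be >= 1")
  list(scenario = scenario, genotypePath = genotypePath,
       clinicalPath = clinicalPath, nSubjects = nSubjects, loci = loci,
       freqThreshold = freqThreshold, pRemove = pRemove,
       entrySet = entrySet, excludeLoci = excludeLoci, B = B,
       aucTimes = aucTimes, seed = as.integer(seed), ties = ties,
       parallel = parallel, cores = cores)
}

#' Run the full prognostic-signature analysis
#'
#' Executes, in order: genotype coding, carrier-frequency filtering,
#' univariate OS and RFS screens, backward-elimination signatures on OS
#' (without and with the mandatory stage covariate), leave-one-out
#' cross-validated risk classification for both models, survival-shuffle
#' permutation tests of both cross-validated statistics, the
#' genotype-permutation comparison against the stage-only model,
#' cross-endpoint validation of both OS-built models on RFS, and
#' time-dependent AUC of the cross-validated prognostic index. Fully
#' deterministic given the configuration.
#'
#' @param config a [runConfig()] list.
#' @param outputDir optional directory; when set, all result tables are
#'   written there as tab-delimited text via [writeAnalysisReport()].
#' @return an [AnalysisReport-class].
#' @export
runAnalysis <- function(config, outputDir = NULL) {
  if (!is.null(config$scenario)) {
    cc <- if (is.null(config$loci))
      makeScenario(config$scenario, nSubjects = config$nSubjects,
                   seed = config$seed)
    else
      makeScenario(config$scenario, nSubjects = config$nSubjects,
                   seed = config$seed, loci = config$loci)
    cohort <- simulateCohort(cc)
    genotypes <- cohort$genotypes
    os <- cohort$os; rfs <- cohort$rfs; stage <- cohort$stage
  } else {
    inp <- readCohortTables(config$genotypePath, config$clinicalPath)
    genotypes <- inp$genotypes
    os <- inp$os; rfs <- inp$rfs; stage <- inp$stage
  }
  coded <- codeAlleles(genotypes)
  filtered <- filterByFrequency(coded, config$freqThreshold)

  ## the modelling matrix withholds excluded loci (screens still see them)
  keep <- colnames(filtered@values)
  if (length(config$excludeLoci)) {
    pat <- paste0("^(", paste(config$excludeLoci, collapse = "|"), ")\\*")
    keep <- keep[!grepl(pat, keep)]
  }
  modelMat <- filtered[, keep]

  uniOS <- univariateScreen(filtered, os, ties = config$ties)
  uniRFS <- univariateScreen(filtered, rfs, ties = config$ties)

  stageCol <- cbind(stage = as.numeric(stage))
  modelOS <- backwardEliminate(modelMat, os, pRemove = config$pRemove,
                               entrySet = config$entrySet,
                               ties = config$ties)
  modelComb <- backwardEliminate(modelMat, os, pRemove = config$pRemove,
                                 mandatory = stageCol,
                                 entrySet = config$entrySet,
                                 ties = config$ties)

  loocvOS <- loocvRiskClassify(modelMat, os, pRemove = config$pRemove,
                               ties = config$ties)
  loocvComb <- loocvRiskClassify(modelMat, os, mandatory = stageCol,
                                 pRemove = config$pRemove,
                                 ties = config$ties)

  permOS <- permutationSignificance(modelMat, os, pRemove = config$pRemove,
                                    B = config$B, seed = config$seed,
                                    ties = config$ties,
                                    parallel = config$parallel,
                                    cores = config$cores)
  permComb <- permutationSignificance(modelMat, os, mandatory = stageCol,
                                      pRemove = config$pRemove,
                                      B = config$B,
                                      seed = config$seed + 1L,
                                      ties = config$ties,
                                      parallel = config$parallel,
                                      cores = config$cores)
  cmp <- compareWithCovariate(modelMat, stage, os,
                              pRemove = config$pRemove, B = config$B,
                              seed = config$seed + 2L, ties = config$ties,
                              parallel = config$parallel,
                              cores = config$cores)

  ceOS <- crossEndpointValidate(modelMat, os, rfs,
                                pRemove = config$pRemove,
                                ties = config$ties)
  ceComb <- crossEndpointValidate(modelMat, os, rfs, mandatory = stageCol,
                                  pRemove = config$pRemove,
                                  ties = config$ties)

  aucRows <- rbind(
    cbind(model = "genotype",
          aucTimeline(loocvOS@pi, os, config$aucTimes)),
    cbind(model = "combined",
          aucTimeline(loocvComb@pi, os, config$aucTimes)))

  report <- new("AnalysisReport", univariateOS = uniOS,
                univariateRFS = uniRFS, modelOS = modelOS,
                modelCombined = modelComb, loocvOS = loocvOS,
                loocvCombined = loocvComb, permutationOS = permOS,
                permutationCombined = permComb, covariateComparison = cmp,
                crossEndpointOS = ceOS, crossEndpointCombined = ceComb,
                aucTimeline = aucRows, config = config)
  if (!is.null(outputDir)) writeAnalysisReport(report, outputDir)
  report
}

#' Write every table of an analysis report to a directory
#'
#' @param report an [AnalysisReport-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writeAnalysisReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(resultsTable(report@univariateOS), "univariate_os.tsv")
  wt(resultsTable(report@univariateRFS), "univariate_rfs.tsv")
  wt(resultsTable(report@modelOS), "model_os.tsv")
  wt(resultsTable(report@modelCombined), "model_os_stage.tsv")
  for (nm in c("loocvOS", "loocvCombined", "crossEndpointOS",
               "crossEndpointCombined")) {
    r <- slot(report, nm)
    wt(data.frame(subject_id = r@subjectIds, pi = r@pi,
                  risk_group = as.character(r@riskGroup)),
       paste0(nm, "_assignments.tsv"))
    wt(cvRiskSummary(r), paste0(nm, "_summary.tsv"))
    wt(kmTable(r@kmLow), paste0(nm, "_km_low.tsv"))
    wt(kmTable(r@kmHigh), paste0(nm, "_km_high.tsv"))
  }
  for (nm in c("permutationOS", "permutationCombined",
               "covariateComparison")) {
    r <- slot(report, nm)
    wt(data.frame(null_statistic = r@nullStatistics),
       paste0(nm, "_null.tsv"))
    wt(data.frame(observed = r@observed, B = r@B, p = r@pValue,
                  seed = r@seed), paste0(nm, "_summary.tsv"))
  }
  wt(report@aucTimeline, "auc_timeline.tsv")
  invisible(dir)
}
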