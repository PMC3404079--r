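#' @include AllClasses.R
NULL

#' Construct a GenotypeTable
#'
#' @param subjectIds unique subject labels.
#' @param calls named list with one n x 2 character matrix of allele calls
#'   per locus (NA = missing call).
#' @param locusKinds named character vector ("multiallelic", "snp",
#'   "microsatellite") per locus; defaults to "multiallelic" for every
#'   locus.
#' @return a [GenotypeTable-class].
#' @export
genotypeTable <- function(subjectIds, calls, locusKinds = NULL) {
  calls <- lapply(calls, function(m) {
    m <- as.matrix(m)
    mode(m) <- "character"
    m
  })
  if (is.null(locusKinds))
    locusKinds <- setNames(rep("multiallelic", length(calls)), names(calls))
  new("GenotypeTable", subjectIds = as.character(subjectIds), calls = calls,
      locusKinds = locusKinds[names(calls)])
}

## presence / homozygosity coding of one multi-allelic (or microsatellite)
## locus; returns a list(values, parent) for the locus
.code_multiallelic <- function(locus, m) {
  alleles <- sort(unique(as.vector(m[!is.na(m)])))
  n <- nrow(m)
  out <- list()
  parent <- character(0)
  for (a in alleles) {
    eq1 <- m[, 1] == a          # NA-propagating comparisons
    eq2 <- m[, 2] == a
    pres <- ifelse(!is.na(eq1) & eq1 | !is.na(eq2) & eq2, 1,
                   ifelse(is.na(eq1) | is.na(eq2), NA, 0))
    hom <- ifelse(is.na(eq1) | is.na(eq2),
                  ## one observed call that is NOT this allele rules
                  ## homozygosity out; otherwise unknown
                  ifelse((!is.na(eq1) & !eq1) | (!is.na(eq2) & !eq2), 0, NA),
                  as.numeric(eq1 & eq2))
    pn <- paste0(locus, "*", a)
    hn <- paste0(pn, "_hom")
    out[[pn]] <- as.numeric(pres)
    out[[hn]] <- as.numeric(hom)
    parent[hn] <- pn
  }
  list(values = out, parent = parent)
}

## genotype-level (diplotype) coding of a SNP locus: one indicator per
## observed unordered genotype, e.g. "CT60*G/G"
.code_snp <- function(locus, m) {
  geno <- ifelse(is.na(m[, 1]) | is.na(m[, 2]), NA_character_,
                 paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "/"))
  levels <- sort(unique(geno[!is.na(geno)]))
  out <- list()
  for (g in levels) {
    gal <- strsplit(g, "/", fixed = TRUE)[[1]]
    v <- as.numeric(geno == g)
    ## with one observed call, a genotype not containing it is excluded
    part <- is.na(geno) & !(is.na(m[, 1]) & is.na(m[, 2]))
    if (any(part)) {
      obs <- ifelse(is.na(m[part, 1]), m[part, 2], m[part, 1])
      v[part] <- ifelse(obs %in% gal, NA, 0)
    }
    out[[paste0(locus, "*", g)]] <- v
  }
  list(values = out, parent = setNames(character(0), character(0)))
}

#' Code raw genotypes into binary design variables
#'
#' For every allele observed at a multi-allelic (HLA) or microsatellite
#' locus, produces a carrier-presence column (1 if the subject carries at
#' least one copy) and a homozygosity column (1 iff both calls equal that
#' allele; 0 for heterozygous carriers and non-carriers). SNP loci are coded
#' as genotype indicators (e.g. \code{"CT60*G/G"} is 1 iff both calls are
#' G). Microsatellite fragment lengths are treated verbatim as alleles of a
#' multi-allelic locus.
#'
#' Missing calls propagate: with one missing call, presence of the observed
#' allele is 1, presence of any other allele is unknown (NA), and
#' homozygosity of the observed allele is unknown (NA) while homozygosity of
#' any other allele is 0.
#'
#' @param genotypes a [GenotypeTable-class].
#' @return an unfiltered [CodedMatrix-class].
#' @examples
#' gt <- genotypeTable(c("P1", "P2"),
#'   list(DRB1 = rbind(c("15", "04"), c("11", "11"))))
#' codedValues(codeAlleles(gt))
#' @export
codeAlleles <- function(genotypes) {
  stopifnot(is(genotypes, "GenotypeTable"))
  validObject(genotypes)
  cols <- list()
  parent <- character(0)
  for (nm in names(genotypes@calls)) {
    kind <- genotypes@locusKinds[[nm]]
    coded <- if (kind == "snp") .code_snp(nm, genotypes@calls[[nm]])
             else .code_multiallelic(nm, genotypes@calls[[nm]])
    cols <- c(cols, coded$values)
    parent <- c(parent, coded$parent)
  }
  v <- do.call(cbind, cols)
  rownames(v) <- genotypes@subjectIds
  cf <- colMeans(v == 1, na.rm = TRUE)
  pv <- setNames(rep(NA_character_, ncol(v)), colnames(v))
  pv[names(parent)] <- parent
  new("CodedMatrix", values = v, carrierFreq = as.numeric(cf),
      parentVariable = pv, dropped = character(0), threshold = NA_real_)
}

#' Filter coded variables by carrier frequency
#'
#' Retains exactly the columns whose carrier frequency (mean over subjects
#' with a non-missing entry) is at least \code{threshold}; discarded column
#' names are recorded in the result. Homozygosity columns are filtered like
#' any other variable unless \code{exemptHomozygosity} is set.
#'
#' @param coded a [CodedMatrix-class].
#' @param threshold carrier-frequency threshold in (0, 1); default 0.10.
#' @param exemptHomozygosity keep a homozygosity column whenever its parent
#'   presence column is kept, regardless of its own frequency.
#' @return a filtered [CodedMatrix-class].
#' @export
filterByFrequency <- function(coded, threshold = 0.10,
                              exemptHomozygosity = FALSE) {
  stopifnot(is(coded, "CodedMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single value in (0, 1)")
  cf <- coded@carrierFreq
  keep <- cf >= threshold
  if (exemptHomozygosity) {
    pv <- coded@parentVariable
    isHom <- !is.na(pv)
    parentKept <- colnames(coded@values)[keep]
    keep <- keep | (isHom & pv %in% parentKept)
  }
  v <- coded@values[, keep, drop = FALSE]
  new("CodedMatrix", values = v, carrierFreq = cf[keep],
      parentVariable = coded@parentVariable[keep],
      dropped = colnames(coded@values)[!keep], threshold = threshold)
}

#' Subset a coded matrix by subject or variable
#'
#' @param x a [CodedMatrix-class].
#' @param i subject index/labels.
#' @param j variable index/labels.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @return a [CodedMatrix-class].
#' @export
setMethod("[", "CodedMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  v2 <- v[i, j, drop = FALSE]
  cf <- colMeans(v2 == 1, na.rm = TRUE)
  new("CodedMatrix", values = v2, carrierFreq = as.numeric(cf),
      parentVariable = x@parentVariable[colnames(v2)],
      dropped = x@dropped, threshold = x@threshold)
})
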