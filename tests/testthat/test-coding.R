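test_that("presence and homozygosity coding follows the stated rules", {
  gt <- genotypeTable(
    c("P1", "P2", "P3"),
    list(DRB1 = rbind(c("15", "04"), c("11", "11"), c("15", "15")),
         C = rbind(c("06", "06"), c("06", "07"), c("03", "04"))))
  cm <- codeAlleles(gt)
  v <- codedValues(cm)
  ## heterozygous carrier: presence 1, homozygosity 0
  expect_equal(v["P1", "DRB1*15"], 1)
  expect_equal(v["P1", "DRB1*15_hom"], 0)
  ## homozygote: both codes 1
  expect_equal(v["P1", "C*06"], 1)
  expect_equal(v["P1", "C*06_hom"], 1)
  expect_equal(v["P3", "DRB1*15_hom"], 1)
  ## non-carrier: both 0
  expect_equal(v["P3", "C*06"], 0)
  expect_equal(v["P3", "C*06_hom"], 0)
})

test_that("a 10-subject toy table codes to the hand-enumerated matrix", {
  calls <- list(
    DRB1 = rbind(c("15", "04"), c("15", "15"), c("04", "04"), c("15", "11"),
                 c("11", "04"), c("11", "11"), c("04", "15"), c("11", "15"),
                 c("04", "11"), c("15", "04")),
    CT60 = rbind(c("G", "G"), c("G", "A"), c("A", "A"), c("A", "G"),
                 c("G", "G"), c("A", "A"), c("G", "A"), c("G", "G"),
                 c("A", "A"), c("A", "G")),
    FOXP3 = rbind(c("336", "338"), c("336", "336"), c("338", "338"),
                  c("336", "340"), c("338", "340"), c("336", "338"),
                  c("340", "340"), c("336", "336"), c("338", "336"),
                  c("340", "338")))
  gt <- genotypeTable(sprintf("P%02d", 1:10), calls,
                      c(DRB1 = "multiallelic", CT60 = "snp",
                        FOXP3 = "microsatellite"))
  v <- codedValues(codeAlleles(gt))

  expect_equal(unname(v[, "DRB1*15"]), c(1,1,0,1,0,0,1,1,0,1))
  expect_equal(unname(v[, "DRB1*15_hom"]), c(0,1,0,0,0,0,0,0,0,0))
  expect_equal(unname(v[, "DRB1*04"]), c(1,0,1,0,1,0,1,0,1,1))
  expect_equal(unname(v[, "DRB1*04_hom"]), c(0,0,1,0,0,0,0,0,0,0))
  expect_equal(unname(v[, "DRB1*11"]), c(0,0,0,1,1,1,0,1,1,0))
  expect_equal(unname(v[, "DRB1*11_hom"]), c(0,0,0,0,0,1,0,0,0,0))
  ## SNPs code as genotype indicators
  expect_equal(unname(v[, "CT60*G/G"]), c(1,0,0,0,1,0,0,1,0,0))
  expect_equal(unname(v[, "CT60*A/G"]), c(0,1,0,1,0,0,1,0,0,1))
  expect_equal(unname(v[, "CT60*A/A"]), c(0,0,1,0,0,1,0,0,1,0))
  ## microsatellite fragment lengths behave as multi-allelic alleles
  expect_equal(unname(v[, "FOXP3*336"]), c(1,1,0,1,0,1,0,1,1,0))
  expect_equal(unname(v[, "FOXP3*336_hom"]), c(0,1,0,0,0,0,0,1,0,0))
  expect_equal(unname(v[, "FOXP3*340"]), c(0,0,0,1,1,0,1,0,0,1))
  ## full column inventory: presence + hom per allele, genotype per SNP
  expect_setequal(colnames(v), c(
    "DRB1*04", "DRB1*04_hom", "DRB1*11", "DRB1*11_hom", "DRB1*15",
    "DRB1*15_hom", "CT60*A/A", "CT60*A/G", "CT60*G/G",
    "FOXP3*336", "FOXP3*336_hom", "FOXP3*338", "FOXP3*338_hom",
    "FOXP3*340", "FOXP3*340_hom"))
})

test_that("missing calls propagate as specified", {
  gt <- genotypeTable(
    c("P1", "P2"),
    list(DRB1 = rbind(c("15", NA), c(NA, NA))))
  v <- codedValues(codeAlleles(gt))
  ## observed call: presence certain, homozygosity unknown
  expect_equal(v["P1", "DRB1*15"], 1)
  expect_true(is.na(v["P1", "DRB1*15_hom"]))
  ## fully missing: everything unknown
  expect_true(is.na(v["P2", "DRB1*15"]))

  gt2 <- genotypeTable(
    c("P1", "P2"),
    list(DRB1 = rbind(c("15", NA), c("04", "04"))))
  v2 <- codedValues(codeAlleles(gt2))
  ## an observed non-matching call rules homozygosity out but leaves
  ## presence of the other allele unknown
  expect_true(is.na(v2["P1", "DRB1*04"]))
  expect_equal(v2["P1", "DRB1*04_hom"], 0)
})

test_that("frequency filter keeps exactly the >= 10% columns", {
  ## 20 subjects; allele A carried by 2 (boundary 10%), B by 1 (5%)
  X <- matrix(0, 20, 2, dimnames = list(sprintf("S%02d", 1:20),
                                        c("L*A", "L*B")))
  X[1:2, "L*A"] <- 1
  X[1, "L*B"] <- 1
  cm <- as_coded(X)
  f <- filterByFrequency(cm, 0.10)
  expect_equal(variableNames(f), "L*A")
  expect_equal(f@dropped, "L*B")
  expect_error(filterByFrequency(cm, 0), "threshold")
  expect_error(filterByFrequency(cm, 1.2), "threshold")
})

test_that("filter retains the analytically expected columns of a designed locus", {
  ## allele carrier probabilities 1-(1-p)^2: 0.059, 0.226, 0.51 around the
  ## 10% threshold with clear margins
  loci <- list(locusSpec("L", "multiallelic",
                         c(a = 0.03, b = 0.12, c = 0.30, oth = 0.55)))
  cfg <- cohortConfig(nSubjects = 1000, loci = loci, seed = 99)
  coded <- codeAlleles(simulateGenotypes(cfg))
  f <- filterByFrequency(coded, 0.10)
  kept <- variableNames(f)
  expect_true(all(c("L*b", "L*c", "L*oth") %in% kept))
  expect_false("L*a" %in% kept)
  expect_false("L*b_hom" %in% kept)   # 0.12^2 is far below 10%
  expect_true("L*oth_hom" %in% kept)  # 0.55^2 = 0.3025
})

test_that("filtering is monotone in the threshold and coding is equivariant", {
  cfg <- cohortConfig(nSubjects = 120, loci = small_panel(c("C", "CT60")),
                      seed = 3)
  gt <- simulateGenotypes(cfg)
  coded <- codeAlleles(gt)
  for (pair in list(c(0.05, 0.10), c(0.10, 0.25), c(0.02, 0.40))) {
    k1 <- variableNames(filterByFrequency(coded, pair[1]))
    k2 <- variableNames(filterByFrequency(coded, pair[2]))
    expect_true(all(k2 %in% k1))
  }
  ## presence dominates homozygosity
  v <- codedValues(coded)
  pv <- coded@parentVariable
  for (hom in names(pv)[!is.na(pv)])
    expect_gte(sum(v[, pv[[hom]]]), sum(v[, hom]))

  ## reordering subjects reorders rows only
  pm <- sample(length(subjectIds(gt)))
  gt2 <- genotypeTable(subjectIds(gt)[pm],
                       lapply(gt@calls, function(m) m[pm, , drop = FALSE]),
                       gt@locusKinds)
  v2 <- codedValues(codeAlleles(gt2))
  expect_equal(v2, v[pm, colnames(v2)])
})
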