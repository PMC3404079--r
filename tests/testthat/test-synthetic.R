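test_that("Hardy-Weinberg sampling has the expected carrier fraction", {
  ## degenerate single-allele locus: everyone homozygous
  cfg <- cohortConfig(nSubjects = 10,
                      loci = list(locusSpec("L", "multiallelic", c(a = 1))),
                      seed = 1)
  gt <- simulateGenotypes(cfg)
  expect_true(all(gt@calls$L == "a"))

  ## biallelic SNP, minor-allele freq 0.2: carrier fraction near
  ## 1 - 0.8^2 = 0.36 (3 binomial SDs at n = 1000)
  cfg2 <- cohortConfig(nSubjects = 1000,
                       loci = list(locusSpec("S", "snp",
                                             c(A = 0.8, G = 0.2))),
                       seed = 2)
  gt2 <- simulateGenotypes(cfg2)
  carrier <- mean(apply(gt2@calls$S == "G", 1, any))
  expect_lt(abs(carrier - 0.36), 3 * sqrt(0.36 * 0.64 / 1000))
})

test_that("allele counts follow the configured multinomial", {
  freqs <- c("01" = 0.1, "02" = 0.25, "03" = 0.4, "04" = 0.25)
  cfg <- cohortConfig(nSubjects = 5000,
                      loci = list(locusSpec("L", "multiallelic", freqs)),
                      seed = 77)
  gt <- simulateGenotypes(cfg)
  counts <- table(factor(as.vector(gt@calls$L), levels = names(freqs)))
  gof <- chisq.test(as.numeric(counts), p = freqs)
  expect_gt(gof$p.value, 0.001)
})

test_that("identical seed gives byte-identical cohorts", {
  cfg <- makeScenario("planted_five_marker", nSubjects = 80, seed = 42)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(c1$genotypes@calls, c2$genotypes@calls)
  expect_identical(survTime(c1$os), survTime(c2$os))
  expect_identical(survEvent(c1$rfs), survEvent(c2$rfs))
  expect_identical(c1$stage, c2$stage)
  ## a different seed changes the draw
  c3 <- simulateCohort(makeScenario("planted_five_marker", nSubjects = 80,
                                    seed = 43))
  expect_false(identical(c1$genotypes@calls, c3$genotypes@calls))
})

test_that("RFS never exceeds OS and censoring behaves as configured", {
  for (seed in 1:5) {
    ch <- simulateCohort(makeScenario("planted_five_marker", nSubjects = 120,
                                      seed = seed))
    expect_true(all(survTime(ch$rfs) <= survTime(ch$os) + 1e-12))
  }
  ## censoring disabled: every event observed
  cfg <- cohortConfig(nSubjects = 200, loci = small_panel(),
                      censoring = list(horizon = Inf, dropoutMax = Inf),
                      seed = 5)
  ch <- simulateCohort(cfg)
  expect_true(all(survEvent(ch$os) == 1))
  expect_true(all(survEvent(ch$rfs) == 1))
})

test_that("generated times reproduce the baseline survivor function", {
  ## no effects, no censoring: the OS Kaplan-Meier estimate converges to
  ## the closed-form baseline survivor (Glivenko-Cantelli at n = 2000)
  cfg <- cohortConfig(nSubjects = 2000, loci = small_panel(),
                      censoring = list(horizon = Inf, dropoutMax = Inf),
                      stagePrevalence = 0, seed = 8)
  ch <- simulateCohort(cfg)
  km <- kaplanMeier(ch$os)
  supDist <- max(abs(km@surv - baselineSurvivor(cfg, km@time)))
  expect_lt(supDist, 0.05)
})

test_that("a planted log(2) effect is recovered by the Cox fit", {
  loci <- list(locusSpec("M", "multiallelic", c(a = 0.25, b = 0.75)))
  cfg <- cohortConfig(nSubjects = 2000, loci = loci,
                      effects = c("M*a" = log(2)),
                      censoring = list(horizon = Inf, dropoutMax = Inf),
                      stagePrevalence = 0, seed = 12)
  ch <- simulateCohort(cfg)
  fit <- fitCox(codedValues(ch$coded)[, "M*a", drop = FALSE], ch$os)
  expect_gt(fit@hr[[1]], 1.8)
  expect_lt(fit@hr[[1]], 2.2)
})

test_that("scenario configurations carry the published effect sizes", {
  null <- makeScenario("null")
  expect_length(null@effects, 0)
  expect_equal(null@stageLogHazard, 0)

  planted <- makeScenario("planted_five_marker")
  expect_length(planted@effects, 5)
  expect_equal(sort(unname(exp(planted@effects))),
               sort(c(0.097, 0.387, 0.449, 1.948, 1.484)), tolerance = 1e-12)
  stage <- makeScenario("stage_only")
  expect_length(stage@effects, 0)
  expect_equal(exp(stage@stageLogHazard), 2.062, tolerance = 1e-12)

  ## the planted markers exist in a coded cohort with carrier frequencies
  ## inside [0.10, 0.35] on average
  ch <- simulateCohort(planted)
  cf <- carrierFrequencies(ch$coded)[names(planted@effects)]
  expect_true(all(!is.na(cf)))
  expect_true(all(cf > 0.05 & cf < 0.45))
})

test_that("misconfigured generators fail loudly", {
  expect_error(locusSpec("L", "multiallelic", c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(locusSpec("L", "snp", c(A = 1)), "at least 2")
  cfg <- cohortConfig(nSubjects = 30, loci = small_panel(),
                      effects = c("NOT*THERE" = 1), seed = 1)
  gt <- simulateGenotypes(cfg)
  coded <- codeAlleles(gt)
  expect_error(simulateSurvival(coded, simulateStage(cfg), cfg),
               "NOT\\*THERE")
})
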