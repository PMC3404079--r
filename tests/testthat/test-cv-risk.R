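## A well-powered small cohort shared by the LOOCV structure tests.
make_cv_fixture <- function(seed = 1, n = 60) {
  sim_simple(n, c(0.4, 0.3, 0.3), c(log(3), log(0.3), 0), cens = 45,
             seed = seed)
}

test_that("LOOCV builds n fold models, each without its held-out subject", {
  fx <- make_cv_fixture()
  cv <- loocvRiskClassify(as_coded(fx$X), fx$surv, collectModels = TRUE)
  n <- length(subjectIds(cv))
  expect_length(cv@foldModels, n)
  expect_equal(sum(cv@groupSizes), n)
  expect_equal(sum(cv@eventCounts), sum(survEvent(fx$surv)))
  expect_true(all(riskGroups(cv) %in% c("low", "high")))

  ## determinism: LOOCV itself involves no randomness
  cv2 <- loocvRiskClassify(as_coded(fx$X), fx$surv)
  expect_identical(riskGroups(cv2), riskGroups(cv))
  expect_equal(prognosticIndices(cv2), prognosticIndices(cv))
})

test_that("held-out assignment follows the >= training-median rule", {
  fx <- make_cv_fixture(seed = 3)
  cv <- loocvRiskClassify(as_coded(fx$X), fx$surv, collectModels = TRUE)
  n <- length(subjectIds(cv))
  for (i in c(1, 5, n)) {
    m <- cv@foldModels[[i]]
    piTrain <- if (length(m$variables))
      as.numeric(fx$X[-i, m$variables, drop = FALSE] %*% m$coefficients)
    else numeric(n - 1)
    piHeld <- if (length(m$variables))
      sum(fx$X[i, m$variables] * m$coefficients) else 0
    expect_equal(unname(prognosticIndices(cv)[i]), piHeld)
    expect_equal(unname(riskGroups(cv)[i] == "high"),
                 piHeld >= median(piTrain))
  }
})

test_that("small cohorts are rejected and degenerate groupings error", {
  fx <- sim_simple(8, 0.4, log(2), seed = 5)
  expect_error(loocvRiskClassify(as_coded(fx$X), fx$surv), "at least 10")

  ## pure-noise data whose folds all yield empty models: every subject
  ## falls in the high-risk group by the >= rule, so the two-group
  ## comparison is undefined
  set.seed(6)
  X <- matrix(rbinom(24 * 2, 1, 0.5), 24, 2)
  sv <- survivalData(seq_len(24), rep(c(0L, 1L), 12))
  expect_error(
    suppressWarnings(loocvRiskClassify(as_coded(X), sv, pRemove = 1e-6)),
    "single risk group")
})

test_that("cross-endpoint validation reduces to LOOCV when endpoints match", {
  fx <- make_cv_fixture(seed = 7)
  cv <- loocvRiskClassify(as_coded(fx$X), fx$surv)
  ce <- crossEndpointValidate(as_coded(fx$X), fx$surv, fx$surv)
  expect_identical(riskGroups(ce), riskGroups(cv))
  expect_equal(ce@logRank@statistic, cv@logRank@statistic)
})

test_that("cross-endpoint groups come from the training endpoint", {
  fx <- make_cv_fixture(seed = 9)
  ## a correlated second endpoint: earlier events, same predictor ordering
  set.seed(10)
  rfsTime <- pmin(survTime(fx$surv), rexp(60, 0.04))
  rfs <- survivalData(rfsTime, rep(1L, 60), endpoint = "RFS")
  ce <- crossEndpointValidate(as_coded(fx$X), fx$surv, rfs)
  cv <- loocvRiskClassify(as_coded(fx$X), fx$surv)
  ## same fold assignments as the OS-only run; only the evaluation differs
  expect_identical(riskGroups(ce), riskGroups(cv))
  expect_equal(ce@endpoint, "RFS")
  expect_equal(sum(ce@eventCounts), sum(survEvent(rfs)))
})

test_that("resubstitution split uses the full-data model and own medians", {
  fx <- make_cv_fixture(seed = 11)
  rs <- resubstitutionRiskClassify(as_coded(fx$X), fx$surv)
  m <- rs@foldModels[[1]]
  pi <- as.numeric(fx$X[, m$variables, drop = FALSE] %*% m$coefficients)
  expect_equal(unname(prognosticIndices(rs)), pi)
  expect_identical(unname(riskGroups(rs) == "high"), pi >= median(pi))
})

test_that("removing a subject changes folds but not the rules", {
  fx <- make_cv_fixture(seed = 13, n = 40)
  cv <- loocvRiskClassify(as_coded(fx$X), fx$surv)
  cvDrop <- loocvRiskClassify(as_coded(fx$X[-40, , drop = FALSE]),
                              survivalData(survTime(fx$surv)[-40],
                                           survEvent(fx$surv)[-40]))
  expect_equal(length(subjectIds(cvDrop)), 39)
  expect_equal(sum(cvDrop@groupSizes), 39)
})

test_that("the run summary mirrors the reporting layout", {
  fx <- make_cv_fixture(seed = 15)
  cv <- loocvRiskClassify(as_coded(fx$X), fx$surv)
  s <- cvRiskSummary(cv)
  expect_equal(s$nLow + s$nHigh, 60)
  expect_equal(s$eventsLow + s$eventsHigh, sum(survEvent(fx$surv)))
  expect_equal(s$LRd, cv@logRank@statistic)
})
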