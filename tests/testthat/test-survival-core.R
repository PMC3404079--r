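test_that("Kaplan-Meier matches hand product-limit computations", {
  ## all events: empirical survivor function
  km <- kaplanMeier(survivalData(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km@time, c(1, 2, 3))
  expect_equal(km@surv, c(2/3, 1/3, 0))

  ## all censored: S = 1 everywhere, no event times
  km0 <- kaplanMeier(survivalData(c(4, 7, 9), c(0, 0, 0)))
  expect_length(km0@time, 0)
  expect_equal(kmSurvivalAt(km0, c(1, 100)), c(1, 1))

  ## mixed censoring: 0.8 * (2/3) = 8/15, then 0
  km2 <- kaplanMeier(survivalData(c(5, 8, 12, 13, 18), c(1, 0, 1, 0, 1)))
  expect_equal(km2@time, c(5, 12, 18))
  expect_equal(km2@surv, c(4/5, 8/15, 0))
  expect_equal(kmSurvivalAt(km2, c(4, 5, 11.9, 12, 17)),
               c(1, 4/5, 4/5, 8/15, 8/15))
})

test_that("Kaplan-Meier equals 1 - ECDF without censoring and matches survfit", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (r in 1:5) {
    n <- 40
    tm <- sample(1:25, n, replace = TRUE)   # ties on purpose
    ev <- rbinom(n, 1, 0.7)
    km <- kaplanMeier(survivalData(tm, ev))
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    evt <- sf$time[sf$n.event > 0]
    expect_equal(km@time, evt)
    expect_equal(km@surv, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  }
  tm <- rexp(30); km <- kaplanMeier(survivalData(tm, rep(1, 30)))
  expect_equal(km@surv, 1 - ecdf(tm)(km@time), tolerance = 1e-12)
})

test_that("log-rank reproduces hand computation and its invariances", {
  sv <- survivalData(c(1, 3, 2, 4), c(1, 1, 1, 1))
  g <- c("A", "A", "B", "B")
  lr <- logRank(sv, g)
  expect_equal(lr@statistic, 8/13, tolerance = 1e-12)

  ## label swap and time shift leave the statistic unchanged
  lr2 <- logRank(sv, rev(g))
  expect_equal(lr2@statistic, lr@statistic, tolerance = 1e-12)
  sv3 <- survivalData(c(1, 3, 2, 4) + 7, c(1, 1, 1, 1))
  expect_equal(logRank(sv3, g)@statistic, lr@statistic, tolerance = 1e-12)

  ## identical (time,event) multisets in both groups: statistic 0
  sv4 <- survivalData(c(2, 5, 9, 2, 5, 9), c(1, 0, 1, 1, 0, 1))
  expect_equal(logRank(sv4, rep(c("A", "B"), each = 3))@statistic, 0,
               tolerance = 1e-12)

  ## single group is an undefined comparison
  expect_error(logRank(sv, rep("A", 4)), "two non-empty groups")
})

test_that("log-rank agrees with survdiff on random censored data", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (r in 1:10) {
    n <- 60
    tm <- sample(1:30, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(ev) == 0) next
    lr <- logRank(survivalData(tm, ev), g)
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(lr@statistic, sd$chisq, tolerance = 1e-9)
  }
})

test_that("fitCox agrees with coxph under both tie corrections", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (r in 1:20) {
    n <- 80
    X <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n), c = rbinom(n, 1, 0.25))
    tm <- round(rexp(n, 0.04 * exp(0.5 * X[, 1] - 0.3 * X[, 2]))) + 1
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 10) next
    for (ties in c("efron", "breslow")) {
      ref <- suppressWarnings(
        survival::coxph(survival::Surv(tm, ev) ~ X, ties = ties,
                        control = survival::coxph.control(eps = 1e-12,
                                                          iter.max = 50)))
      if (any(abs(coef(ref)) > 8)) next
      fit <- fitCox(X, survivalData(tm, ev), ties = ties)
      expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
      expect_equal(unname(fit@se), unname(sqrt(diag(vcov(ref)))),
                   tolerance = 1e-7)
      expect_equal(fit@logLik, ref$loglik[2], tolerance = 1e-8)
    }
  }
})

test_that("fitCox satisfies its stationarity and likelihood-gain guarantees", {
  set.seed(41)
  n <- 60
  X <- cbind(x = rbinom(n, 1, 0.3), z = rnorm(n))
  tm <- rexp(n, 0.05 * exp(0.6 * X[, 1]))
  sv <- survivalData(tm, rep(1L, n))
  fit <- fitCox(X, sv)
  expect_true(fit@converged)
  expect_gte(fit@logLik, fit@logLikNull)
  ## score at the solution vanishes: perturbing any coefficient lowers the
  ## likelihood (numeric stationarity check via the grid oracle form)
  ll <- function(b) {
    eta <- as.numeric(X %*% b)
    s <- 0
    for (i in which(sv@event == 1))
      s <- s + eta[i] - log(sum(exp(eta[sv@time >= sv@time[i]])))
    s
  }
  b <- coef(fit)
  for (d in list(c(1e-4, 0), c(-1e-4, 0), c(0, 1e-4), c(0, -1e-4)))
    expect_lte(ll(b + d), ll(b) + 1e-10)
})

test_that("fitCox is scale-equivariant and row-permutation invariant", {
  set.seed(51)
  n <- 50
  x <- rnorm(n)
  tm <- rexp(n, 0.05 * exp(0.4 * x))
  sv <- survivalData(tm, rep(1L, n))
  f1 <- fitCox(cbind(x = x), sv)
  f10 <- fitCox(cbind(x = 10 * x), sv)
  expect_equal(unname(coef(f10)), unname(coef(f1)) / 10, tolerance = 1e-6)
  expect_equal(unname(f10@z), unname(f1@z), tolerance = 1e-6)

  pm <- sample(n)
  f2 <- fitCox(cbind(x = x[pm]), survivalData(tm[pm], rep(1L, n)))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-9)
})

test_that("fitCox reports degenerate designs by name", {
  sv <- survivalData(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 0))
  X <- cbind(good = c(0, 1, 0, 1, 0, 1), flat = rep(1, 6))
  expect_error(fitCox(X, sv), "flat")
  ## perfect separation: the carrier group has no events
  Xs <- cbind(sep = c(0, 0, 0, 0, 1, 1))
  svs <- survivalData(c(1, 2, 3, 4, 9, 10), c(1, 1, 1, 1, 0, 0))
  expect_error(fitCox(Xs, svs), "monotone|diverged")
  expect_error(fitCox(cbind(x = c(NA, 1, 0, 1, 0, 1)), sv), "missing")
})

test_that("exp(beta) recovers the generating hazard ratio at n = 2000", {
  sim <- sim_simple(2000, 0.4, log(2), seed = 61)
  fit <- fitCox(sim$X[, 1, drop = FALSE], sim$surv)
  expect_gt(fit@hr[[1]], 1.8)
  expect_lt(fit@hr[[1]], 2.2)
})
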