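test_that("duplicate variables receive identical univariate statistics", {
  sim <- sim_simple(150, c(0.3, 0.3), c(log(2), 0), cens = 40, seed = 71)
  X <- cbind(sim$X, dup = sim$X[, 1])
  rep <- univariateScreen(as_coded(X), sim$surv)
  t <- rep@table
  expect_equal(t$p[t$variable == "m01"], t$p[t$variable == "dup"])
  expect_equal(t$hr[t$variable == "m01"], t$hr[t$variable == "dup"])
  expect_true(all(diff(t$p) >= 0))   # sorted by p
})

test_that("univariate screen has power against a planted HR of 2", {
  hits <- 0
  for (r in 1:100) {
    sim <- sim_simple(300, 0.3, log(2), cens = 28, seed = 700 + r)
    rep <- univariateScreen(as_coded(sim$X), sim$surv)
    hits <- hits + rep@table$significant[1]
  }
  expect_gte(hits, 90)
})

test_that("univariate screen holds its type-I error on null markers", {
  hits <- 0
  for (r in 1:200) {
    sim <- sim_simple(150, 0.3, 0, cens = 30, seed = 900 + r)
    rep <- univariateScreen(as_coded(sim$X), sim$surv)
    hits <- hits + rep@table$significant[1]
  }
  band <- qbinom(c(0.025, 0.975), 200, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("a single significant variable survives as the whole model", {
  sim <- sim_simple(200, 0.4, log(3), cens = 40, seed = 81)
  m <- backwardEliminate(as_coded(sim$X), sim$surv, pRemove = 0.10)
  expect_equal(variableNames(m), "m01")
  expect_lt(m@p[1], 0.10)
  expect_false(m@emptyModel)
})

test_that("backward elimination keeps planted markers and sheds nulls", {
  bothKept <- 0
  nullKept <- integer(8)
  for (r in 1:100) {
    sim <- sim_simple(400, rep(0.3, 10),
                      c(log(2), log(0.4), rep(0, 8)), cens = 35,
                      seed = 1100 + r)
    m <- suppressWarnings(backwardEliminate(as_coded(sim$X), sim$surv))
    sel <- variableNames(m)
    bothKept <- bothKept + all(c("m01", "m02") %in% sel)
    nullKept <- nullKept + (sprintf("m%02d", 3:10) %in% sel)
  }
  expect_gte(bothKept, 80)
  expect_lte(mean(nullKept / 100), 8 * 0.10 / 8 + 0.05)
})

test_that("an all-null matrix usually eliminates every variable", {
  empties <- 0
  for (r in 1:50) {
    sim <- sim_simple(100, rep(0.3, 5), rep(0, 5), cens = 30,
                      seed = 1300 + r)
    m <- suppressWarnings(backwardEliminate(as_coded(sim$X), sim$surv))
    empties <- empties + m@emptyModel
  }
  expect_gt(empties, 25)
})

test_that("mandatory covariates are never removed", {
  sim <- sim_simple(150, rep(0.3, 4), rep(0, 4), cens = 30, seed = 85)
  stage <- rbinom(150, 1, 0.5)
  m <- suppressWarnings(
    backwardEliminate(as_coded(sim$X), sim$surv,
                      mandatory = cbind(stage = stage)))
  expect_true("stage" %in% variableNames(m))
})

test_that("elimination is invariant to subject row order", {
  sim <- sim_simple(150, rep(0.3, 6), c(log(2), rep(0, 5)), cens = 30,
                    seed = 87)
  m1 <- suppressWarnings(backwardEliminate(as_coded(sim$X), sim$surv))
  pm <- sample(150)
  m2 <- suppressWarnings(
    backwardEliminate(as_coded(sim$X[pm, ]),
                      survivalData(survTime(sim$surv)[pm],
                                   survEvent(sim$surv)[pm])))
  expect_equal(variableNames(m1), variableNames(m2))
  expect_equal(m1@coefficients, m2@coefficients, tolerance = 1e-9)
})

test_that("the prognostic index is the coefficient-weighted marker sum", {
  empty <- new("PrognosticModel", variables = character(0),
               coefficients = numeric(0), se = numeric(0), p = numeric(0),
               hr = numeric(0), ciLower = numeric(0), ciUpper = numeric(0),
               emptyModel = TRUE, droppedForFit = character(0),
               nUsed = 0L)
  expect_equal(prognosticIndex(empty, c(a = 1, b = 0)), 0)

  two <- new("PrognosticModel", variables = c("a", "b"),
             coefficients = c(0.7, -0.8), se = c(0.1, 0.1),
             p = c(0.01, 0.01), hr = exp(c(0.7, -0.8)),
             ciLower = c(1, 0.3), ciUpper = c(3, 0.6),
             emptyModel = FALSE, droppedForFit = character(0), nUsed = 10L)
  expect_equal(prognosticIndex(two, c(a = 1, b = 0)), 0.7)
  expect_error(prognosticIndex(two, c(a = 1)), "lacks model variable")
  expect_error(prognosticIndex(two, c(a = 1, b = NA)), "missing")

  ## a published-style five-marker signature: a carrier of only the two
  ## adverse markers scores the sum of their log hazard ratios
  five <- new("PrognosticModel",
              variables = c("B*38", "C*15", "C*03", "DRB1*15", "CT60*G/G"),
              coefficients = log(c(0.097, 0.387, 0.449, 1.948, 1.484)),
              se = rep(0.3, 5), p = rep(0.02, 5),
              hr = c(0.097, 0.387, 0.449, 1.948, 1.484),
              ciLower = rep(0.1, 5), ciUpper = rep(3, 5),
              emptyModel = FALSE, droppedForFit = character(0),
              nUsed = 284L)
  x <- setNames(c(0, 0, 0, 1, 1), five@variables)
  expect_equal(prognosticIndex(five, x), log(1.948) + log(1.484),
               tolerance = 1e-12)
  expect_equal(prognosticIndex(five, x), 1.0615, tolerance = 1e-4)

  ## additivity over disjoint active sets
  x1 <- setNames(c(1, 0, 0, 0, 0), five@variables)
  x2 <- setNames(c(0, 1, 1, 0, 0), five@variables)
  expect_equal(prognosticIndex(five, x1 + x2),
               prognosticIndex(five, x1) + prognosticIndex(five, x2),
               tolerance = 1e-12)
})

test_that("the prognostic index tracks the true linear predictor", {
  hits <- 0
  for (r in 1:20) {
    sim <- sim_simple(250, rep(0.3, 6),
                      c(log(2.2), log(0.4), rep(0, 4)), cens = 35,
                      seed = 1500 + r)
    m <- suppressWarnings(backwardEliminate(as_coded(sim$X), sim$surv))
    if (m@emptyModel) next
    pi <- prognosticIndex(m, sim$X)
    eta <- as.numeric(sim$X %*% c(log(2.2), log(0.4), rep(0, 4)))
    hits <- hits + (cor(pi, eta, method = "kendall") > 0)
  }
  expect_gte(hits, 19)
})
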