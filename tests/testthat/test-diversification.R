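test_that("pure-birth likelihood matches the closed-form hand computation", {
  bt <- structure(c(10, 6, 3), n = 4L)
  expect_equal(divLoglik(bt, "pure_birth", c(r1 = 2 / 29)),
               log(2 * 2 / 29) + log(3 * 2 / 29) - (2 / 29) * 29,
               tolerance = 1e-12)
  expect_equal(divLoglik(bt, "pure_birth", c(r1 = 2 / 29)), -5.5565,
               tolerance = 1e-4)
})

test_that("nested models agree in their shared limits", {
  for (seed in 1:3) {
    bt <- branchingTimes(randomYuleTree(12, seed = seed))
    lam <- 0.07
    expect_equal(divLoglik(bt, "birth_death", c(r1 = lam, a = 0)),
                 divLoglik(bt, "pure_birth", c(r1 = lam)), tolerance = 1e-9)
    expect_equal(divLoglik(bt, "yule_3rate",
                           list(r1 = lam, r2 = lam, r3 = lam, s1 = 9, s2 = 4)),
                 divLoglik(bt, "pure_birth", c(r1 = lam)), tolerance = 1e-9)
    expect_equal(divLoglik(bt, "yule_2rate", list(r1 = lam, r2 = lam, s1 = 7)),
                 divLoglik(bt, "pure_birth", c(r1 = lam)), tolerance = 1e-9)
  }
})

test_that("fitted models respect nesting monotonicity", {
  for (seed in 4:6) {
    bt <- branchingTimes(randomYuleTree(15, seed = seed))
    pb <- fitDivModel(bt, "pure_birth")$lnL
    expect_gte(fitDivModel(bt, "birth_death")$lnL, pb - 1e-6)
    y2 <- fitDivModel(bt, "yule_2rate")$lnL
    y3 <- fitDivModel(bt, "yule_3rate")$lnL
    expect_gte(y2, pb - 1e-6)
    expect_gte(y3, y2 - 1e-6)
  }
})

test_that("the closed-form Yule MLE matches the numeric optimum", {
  bt <- structure(c(10, 6, 3), n = 4L)
  expect_equal(fitDivModel(bt, "pure_birth")$pars$r1, 2 / 29, tolerance = 1e-12)
  for (seed in 1:4) {
    bt <- branchingTimes(randomYuleTree(10 + seed, seed = seed))
    lamHat <- fitDivModel(bt, "pure_birth")$pars$r1
    lamNum <- stats::optimize(function(l) divLoglik(bt, "pure_birth", c(r1 = l)),
                              c(1e-6, 1), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(lamHat, lamNum, tolerance = 1e-6)
  }
})

test_that("likelihoods match the quadrature oracle on small trees", {
  for (seed in 1:2) {
    bt <- branchingTimes(randomYuleTree(8, seed = 20 + seed))
    expect_equal(divLoglik(bt, "yule_3rate",
                           list(r1 = 0.02, r2 = 0.2, r3 = 0.05,
                                s1 = bt[1] * 0.6, s2 = bt[1] * 0.3)),
                 oracleDivLoglik(bt, function(a, N)
                   if (a > bt[1] * 0.6) 0.02 else if (a > bt[1] * 0.3) 0.2 else 0.05),
                 tolerance = 1e-6)
    expect_equal(divLoglik(bt, "DDX", list(r1 = 0.1, xp = -0.15)),
                 oracleDivLoglik(bt, function(a, N) 0.1 * N^(0.15)),
                 tolerance = 1e-6)
  }
})

test_that("information criteria follow their definitions", {
  expect_equal(unname(aicScores(-54.49, 1)["AIC"]), 110.98)
  expect_equal(round(unname(aicScores(-54.49, 1)["AIC"]), 1), 111.0)
  expect_equal(round(unname(aicScores(-44.29, 5)["AIC"]), 1), 98.6)
  expect_equal(unname(aicScores(0, 0)["AIC"]), 0)
  sc <- aicScores(-10, 2, nObs = 20)
  expect_equal(unname(sc["AICc"]), unname(sc["AIC"]) + 2 * 2 * 3 / 17)
  expect_error(aicScores(-10, 5, nObs = 6), "AICc undefined")
})

test_that("model-selection tables report dAIC against the best model", {
  bt <- branchingTimes(getPreset()$tree)
  tab <- modelSelectionTable(bt)
  expect_equal(min(tab$dAIC), 0)
  expect_equal(tab$dAIC, tab$AIC - min(tab$AIC))
  expect_equal(tab$model[1], "pure_birth")
  # every fit satisfies AIC = -2 lnL + 2k
  fits <- attr(tab, "fits")
  for (f in fits) expect_equal(f$AIC, -2 * f$lnL + 2 * f$k, tolerance = 1e-9)
})

test_that("model selection prefers pure birth among constant-rate models on constant-rate data", {
  # multi-rate profile fits are selection-biased on raw AIC(c), which is why
  # rate shifts are judged by the simulation-calibrated shiftTest() instead;
  # within the constant-rate class the criterion is consistent
  wins <- vapply(1:25, function(i) {
    bt <- branchingTimes(randomYuleTree(40, T = 40, lambda = 0.08,
                                        seed = 500 + i))
    tab <- modelSelectionTable(bt, models = c("pure_birth", "birth_death",
                                              "DDL", "DDX"),
                               criterion = "AICc")
    tab$model[which.min(tab$AICc)] == "pure_birth"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("the shift test is reproducible and defines its statistic correctly", {
  tr <- getPreset()$tree
  s1 <- shiftTest(tr, replicates = 150, seed = 5)
  s2 <- shiftTest(tr, replicates = 150, seed = 5)
  expect_identical(s1$null, s2$null)
  expect_equal(s1$p.value,
               (1 + sum(s1$null >= s1$observed)) / (1 + 150))
  bt <- branchingTimes(tr)
  expect_equal(s1$observed,
               fitDivModel(bt, "pure_birth")$AICc -
                 min(fitDivModel(bt, "yule_2rate")$AICc,
                     fitDivModel(bt, "yule_3rate")$AICc))
})

test_that("Weibull window analysis nests the constant-rate model at beta = 1", {
  bt <- branchingTimes(getPreset()$tree)
  expect_equal(divLoglik(bt, "weibull_decline",
                         list(b = 15, beta = 1, windowStart = bt[1])),
               divLoglik(bt, "pure_birth", c(r1 = 1 / 15)), tolerance = 1e-9)
  fw <- fitWeibullWindow(bt, 41.2)
  expect_gte(fw$chisq, 0)
  expect_equal(fw$p.value, stats::pchisq(fw$chisq, 1, lower.tail = FALSE))
  # windowed constant fit at the crown equals the unwindowed fit
  expect_equal(fitDivModel(bt, "pure_birth", window = bt[1])$lnL,
               fitDivModel(bt, "pure_birth")$lnL, tolerance = 1e-9)
  # decelerating-rate data recover beta > 1
  hits <- vapply(1:25, function(i) {
    tri <- simulateTree(simConfig(crownAge = 30, nTip = 40,
                                  lambda = c(0.35, 0.12, 0.04),
                                  shiftAges = c(22, 12)), seed = 700 + i)
    fitWeibullWindow(branchingTimes(tri), 30)$beta > 1
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
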