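test_that("BiSSE factorizes into Yule x Mk when rates are state-independent", {
  for (n in c(8, 25, 50)) {
    tr <- randomYuleTree(n, T = 25, lambda = 0.12, seed = n)
    Q <- matrix(c(-0.04, 0.04, 0.04, -0.04), 2, byrow = TRUE,
                dimnames = list(c("0", "1"), c("0", "1")))
    stChar <- simulateDiscreteTrait(tr, Q, seed = n + 1)
    st <- setNames(as.integer(stChar), names(stChar))
    lam <- 0.09
    bl <- bisseLoglik(tr, st, bisseParams(lam, lam, 0, 0, 0.04, 0.04),
                      rootWeighting = "equal")
    pb <- divLoglik(branchingTimes(tr), "pure_birth", c(r1 = lam))
    mk <- mkLoglik(tr, stChar, Q)
    expect_equal(bl, pb - lfactorial(n - 1) + mk, tolerance = 1e-5)
  }
})

test_that("BiSSE matches the independent ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- bisseParams(0.07, 0.12, 0.01, 0.03, 0.04, 0.02, rho0 = 0.9, rho1 = 0.8)
  tr2 <- parseNewick("(A:3,B:3);")
  st2 <- setNames(c(0, 1), c("A", "B"))
  expect_equal(bisseLoglik(tr2, st2, p), oracleBisseLoglik(tr2, st2, p),
               tolerance = 1e-6)
  tr <- randomYuleTree(8, T = 15, lambda = 0.12, seed = 2)
  set.seed(9)
  st <- setNames(sample(0:1, 8, TRUE), tr$tip.label)
  expect_equal(bisseLoglik(tr, st, p), oracleBisseLoglik(tr, st, p),
               tolerance = 1e-5)
  st[3] <- NA   # missing state enters as ambiguity
  expect_equal(bisseLoglik(tr, st, p), oracleBisseLoglik(tr, st, p),
               tolerance = 1e-5)
})

test_that("the likelihood is continuous in the sampling fractions", {
  tr <- randomYuleTree(12, seed = 3)
  set.seed(4)
  st <- setNames(sample(0:1, 12, TRUE), tr$tip.label)
  l1 <- bisseLoglik(tr, st, bisseParams(0.06, 0.1, 0, 0, 0.02, 0.02))
  l2 <- bisseLoglik(tr, st, bisseParams(0.06, 0.1, 0, 0, 0.02, 0.02,
                                        rho0 = 0.9999, rho1 = 0.9999))
  expect_lt(abs(l1 - l2), 1e-2)
})

test_that("polytomies and non-binary states are rejected", {
  poly <- parseNewick("(A:2,B:2,C:2);")
  expect_error(bisseLoglik(poly, setNames(c(0, 1, 0), c("A", "B", "C")),
                           bisseParams(0.1, 0.1, 0, 0, 0.1, 0.1)),
               "bifurcating")
  tr <- randomYuleTree(5, seed = 5)
  expect_error(bisseLoglik(tr, setNames(c(0, 1, 2, 0, 1), tr$tip.label),
                           bisseParams(0.1, 0.1, 0, 0, 0.1, 0.1)), "0/1")
})

test_that("the Yule-constrained model pair behaves like a nested LRT", {
  p <- bisseParams(0.010, 0.088, 0, 0, 0.01, 0.01)
  s <- simulateBisseTree(p, nTip = 120, seed = 6)
  f <- fitSseModels(s$tree, s$states)
  expect_gte(f$LR, 0)
  expect_equal(f$p.value, stats::pchisq(f$LR, 1, lower.tail = FALSE))
  expect_gt(f$lambda1, f$lambda0)   # strong simulated contrast is recovered
  expect_error(fitSseModels(s$tree, s$states[1:5]), "at least 10")
})

test_that("lambda_Yule matches the closed-form Yule MLE in the neutral limit", {
  tr <- simulateTree(simConfig(crownAge = 40, nTip = 30, lambda = 0.08),
                     seed = 5)
  f <- fitSseModels(tr, setNames(rep(0L, 30), tr$tip.label))
  bt <- branchingTimes(tr)
  lamCF <- (attr(bt, "n") - 2) / (bt[1] + sum(bt))
  expect_equal(f$lambdaYule, lamCF, tolerance = 1e-3)
})

test_that("unequal sampling fractions shift rates for the undersampled state upward", {
  p <- bisseParams(0.05, 0.05, 0, 0, 0.02, 0.02)
  s <- simulateBisseTree(p, nTip = 80, seed = 6)
  f1 <- fitSseModels(s$tree, s$states, samplingFractions = c(1, 1))
  f2 <- fitSseModels(s$tree, s$states, samplingFractions = c(0.7, 1))
  expect_gt(f2$lambda0, f1$lambda0)
})
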