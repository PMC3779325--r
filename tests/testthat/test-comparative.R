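test_that("Mk pruning and marginal reconstruction match exhaustive enumeration", {
  skip_if_not_installed("Matrix")
  tr5 <- randomYuleTree(5, T = 10, lambda = 0.15, seed = 4)
  Q <- matrix(c(-0.12, 0.08, 0.04, 0.05, -0.1, 0.05, 0.02, 0.07, -0.09), 3,
              byrow = TRUE, dimnames = list(1:3, 1:3))
  sts <- setNames(c("1", "3", "2", "1", "3"), tr5$tip.label)
  tp <- bathydiv:::.tipPartials(tr5, sts, rownames(Q))
  expect_equal(mkLoglik(tr5, sts, Q),
               oracleMkLoglik(tr5, tp, Q, rep(1 / 3, 3)), tolerance = 1e-8)
  asr <- mkAsr(tr5, sts, Q = Q)
  expect_equal(unname(asr$nodeProbs),
               unname(oracleMkMarginals(tr5, tp, Q, rep(1 / 3, 3))),
               tolerance = 1e-8)
  expect_equal(rowSums(asr$nodeProbs), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)

  # multistate (ambiguous) tips, as produced by depth-bin coding
  stsL <- list(c("1", "2"), "3", "2", c("2", "3"), "1")
  names(stsL) <- tr5$tip.label
  tpL <- bathydiv:::.tipPartials(tr5, stsL, rownames(Q))
  expect_equal(mkLoglik(tr5, stsL, Q),
               oracleMkLoglik(tr5, tpL, Q, rep(1 / 3, 3)), tolerance = 1e-8)
})

test_that("Mk reconstruction limits behave as expected", {
  tr2 <- parseNewick("(A:2,B:2);")
  Q <- matrix(c(-0.1, 0.1, 0.1, -0.1), 2, dimnames = list(0:1, 0:1))
  asr <- mkAsr(tr2, setNames(c("0", "1"), c("A", "B")), Q = Q)
  expect_equal(unname(asr$nodeProbs[1, ]), c(0.5, 0.5), tolerance = 1e-9)

  tr <- randomYuleTree(6, seed = 6)
  Q0 <- matrix(c(-1e-9, 1e-9, 1e-9, -1e-9), 2, dimnames = list(0:1, 0:1))
  asr0 <- mkAsr(tr, setNames(rep("0", 6), tr$tip.label), Q = Q0)
  expect_true(all(asr0$nodeProbs[, "0"] > 0.999))
  expect_error(fitMk(tr, setNames(rep("0", 6), tr$tip.label)), "constant")
})

test_that("Brownian reconstruction gives GLS means and recovers the rate", {
  star <- parseNewick("(A:1,B:1,C:1);")
  ba <- bmAsr(star, setNames(c(1, 2, 3), c("A", "B", "C")))
  expect_equal(ba$rootMean, 2, tolerance = 1e-9)
  # root mean invariant under relabelling on a symmetric tree
  ba2 <- bmAsr(star, setNames(c(3, 1, 2), c("A", "B", "C")))
  expect_equal(ba$rootMean, ba2$rootMean, tolerance = 1e-12)

  skip_if_not_installed("phytools")
  tr <- randomYuleTree(12, seed = 9)
  y <- simulateContinuousTrait(tr, 0.3, rootValue = 1, seed = 10)
  ba3 <- bmAsr(tr, y)
  fa <- phytools::fastAnc(tr, y)
  expect_equal(unname(ba3$ancestralMeans), unname(as.numeric(fa)),
               tolerance = 1e-6)
  expect_true(all(ba3$ancestralVars >= 0))
})

test_that("depth discretization follows the half-open 500-m binning", {
  expect_equal(discretizeDepth(300, 1200), 1:3)
  expect_equal(discretizeDepth(700, 700), 2L)
  expect_equal(discretizeDepth(0, 499), 1L)
  expect_equal(discretizeDepth(500, 500), 2L)
  b <- discretizeDepth(100, 4400, globalMax = 4500)
  expect_equal(attr(b, "nBins"), 9L)
  expect_error(discretizeDepth(-5, 100), "depthMin")
  sets <- depthStateSets(getPreset()$traits)
  nb <- attr(sets, "nBins")
  expect_lte(nb, 9L)
  for (s in sets) if (!is.null(s)) {
    expect_true(all(diff(s) == 1))      # contiguous
    expect_true(all(s >= 1 & s <= nb))
  }
})

test_that("Pagel's dependent-model likelihood matches the joint-chain oracle", {
  skip_if_not_installed("Matrix")
  tr5 <- randomYuleTree(5, T = 10, lambda = 0.15, seed = 4)
  x <- setNames(c(0, 1, 0, 1, 1), tr5$tip.label)
  y <- setNames(c(1, 1, 0, 0, 1), tr5$tip.label)
  j <- setNames(1L + y + 2L * x, tr5$tip.label)
  r8 <- c(0.03, 0.06, 0.02, 0.05, 0.04, 0.07, 0.01, 0.08)
  po <- bathydiv:::.postorderEdges(tr5)
  tL <- matrix(0, 5, 4); tL[cbind(1:5, j[tr5$tip.label])] <- 1
  expect_equal(
    -bathydiv:::pagel_nll_cpp(log(r8), TRUE, po$edge, po$len, 5, tL),
    oraclePagelLoglik(tr5, j, bathydiv:::.pagelQ(r8, TRUE)),
    tolerance = 1e-8)
  # independent model = dependent model with tied rates
  r4 <- c(0.03, 0.06, 0.04, 0.01)
  expect_equal(
    bathydiv:::pagel_nll_cpp(log(r4), FALSE, po$edge, po$len, 5, tL),
    bathydiv:::pagel_nll_cpp(log(r4[c(1, 1, 2, 2, 3, 3, 4, 4)]), TRUE,
                             po$edge, po$len, 5, tL),
    tolerance = 1e-10)
})

test_that("Pagel's test detects dependence and rejects degenerate traits", {
  tr <- randomYuleTree(40, T = 40, lambda = 0.1, seed = 20)
  # strongly dependent pair: y switches only when x = 1
  Qd <- bathydiv:::.pagelQ(c(0.05, 0.05, 0.01, 0.01, 0.002, 0.6, 0.002, 0.01),
                           TRUE)
  dimnames(Qd) <- list(1:4, 1:4)
  j <- simulateDiscreteTrait(tr, Qd, rootProbs = c(1, 0, 0, 0), seed = 23)
  x <- as.integer(j %in% c("3", "4")); names(x) <- names(j)
  y <- as.integer(j %in% c("2", "4")); names(y) <- names(j)
  pg <- pagelTest(tr, x, y, sims = 150, seed = 22, restarts = 2)
  expect_gte(pg$dlogL, 0)
  expect_lt(pg$p.value, 0.1)
  expect_error(pagelTest(tr, setNames(rep(0, 40), names(x)), y),
               "degenerate")
})

test_that("phylogenetic ANOVA equals ordinary ANOVA on a star phylogeny", {
  set.seed(30)
  star <- parseNewick(paste0("(", paste(sprintf("t%d:1", 1:30), collapse = ","),
                             ");"))
  y <- setNames(rnorm(30), star$tip.label)
  g <- setNames(rep(c("a", "b", "c"), each = 10), star$tip.label)
  pa <- phyloAnova(star, y, g, sims = 5000, seed = 31)
  expect_equal(pa$p.phylo, pa$p.parametric, tolerance = 0.02)
  expect_error(phyloAnova(star, y, setNames(c("a", rep("b", 29)),
                                            star$tip.label)), "singleton")
})

test_that("phylogenetic ANOVA detects strong group shifts on the tree", {
  tr <- randomYuleTree(40, T = 40, lambda = 0.1, seed = 33)
  hits <- vapply(1:15, function(i) {
    y <- simulateContinuousTrait(tr, 0.05, seed = 40 + i)
    g <- setNames(rep(c("a", "b"), each = 20), tr$tip.label)
    y[g == "b"] <- y[g == "b"] + 6 * sd(y)
    phyloAnova(tr, y, g, sims = 300, seed = 60 + i)$p.phylo < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("PGLS reduces to OLS on a star tree and matches nlme elsewhere", {
  set.seed(50)
  star <- parseNewick(paste0("(", paste(sprintf("t%d:1", 1:20), collapse = ","),
                             ");"))
  x <- setNames(rnorm(20), star$tip.label)
  y <- setNames(2 * x + rnorm(20), star$tip.label)
  g <- pglsFit(star, y, x)
  ols <- summary(lm(y ~ x))
  expect_equal(unname(g$coefficients), unname(coef(lm(y ~ x))),
               tolerance = 1e-8)
  expect_equal(unname(g$t), unname(ols$coefficients[, "t value"]),
               tolerance = 1e-8)

  skip_if_not_installed("nlme")
  tr <- randomYuleTree(20, T = 30, lambda = 0.1, seed = 51)
  xx <- simulateContinuousTrait(tr, 0.2, seed = 52)
  yy <- 1.5 * xx + simulateContinuousTrait(tr, 0.1, seed = 53)
  gp <- pglsFit(tr, yy, xx)
  d <- data.frame(yy = yy[tr$tip.label], xx = xx[tr$tip.label])
  rownames(d) <- tr$tip.label
  gl <- suppressWarnings(
    nlme::gls(yy ~ xx, data = d,
              correlation = ape::corBrownian(1, tr, form = ~1)))
  expect_equal(unname(gp$coefficients), unname(coef(gl)), tolerance = 1e-6)
  expect_equal(unname(gp$t),
               unname(summary(gl)$tTable[, "t-value"]), tolerance = 1e-5)
  expect_error(pglsFit(tr, yy, setNames(rep(1, 20), tr$tip.label)),
               "singular")
})

test_that("the Mann-Whitney depth comparison uses exact small-sample p-values", {
  d <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  g <- setNames(rep(c("organic-fall", "vent/seep"), each = 3), names(d))
  mw <- mannWhitneyDepth(d, g)
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p.value, 0.1, tolerance = 1e-12)

  same <- mannWhitneyDepth(setNames(c(1, 2, 3, 1, 2, 3), paste0("s", 1:6)), g)
  expect_equal(same$p.value, 1)

  # shifted distributions are detected
  hits <- vapply(1:20, function(i) {
    set.seed(70 + i)
    a <- rnorm(20); b <- rnorm(20) + 3
    dd <- setNames(c(a, b), paste0("x", 1:40))
    gg <- setNames(rep(c("of", "vs"), each = 20), names(dd))
    mannWhitneyDepth(dd, gg)$p.value < 0.01
  }, logical(1))
  expect_gt(mean(hits), 0.95)
  expect_error(mannWhitneyDepth(d, setNames(rep("a", 6), names(d))),
               "2 non-empty groups")
})
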