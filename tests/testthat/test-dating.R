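test_that("offset-exponential soft bounds reproduce their defining quantile", {
  expect_equal(round(calibrationSoftBound(45, 1.2), 1), 48.6)
  expect_equal(round(calibrationSoftBound(25.2, 0.7), 1), 27.3)
  expect_equal(calibrationSoftBound(45, 1.2, quantile = 1e-12), 45,
               tolerance = 1e-9)
  expect_error(calibrationSoftBound(45, 1.2, quantile = 1.2), "quantile")

  # soft bound is the exact inverse of the implemented CDF
  for (q in c(0.5, 0.9, 0.95, 0.999)) {
    b <- calibrationSoftBound(15.1, 1.3, q)
    expect_equal(calibrationPriorCDF(b, 15.1, 1.3), q, tolerance = 1e-12)
  }
  expect_equal(calibrationPriorDensity(14, 15.1, 1.3), 0)
  expect_equal(calibrationPriorDensity(15.1, 15.1, 1.3), 1 / 1.3)
})

test_that("NPRS recovers a clock-like phylogram exactly", {
  # clock-like: substitution lengths proportional to time (rate 0.05/Myr)
  chronTrue <- bathydiv:::.treeFromAges(c(2, 1.2, 0.5, 0.3))
  phy <- chronTrue
  phy$edge.length <- phy$edge.length * 0.05
  out <- nprsSmooth(phy, list(list(taxa = "root", min = 2, max = 2)),
                    restarts = 4, seed = 1)
  trueAges <- bathydiv:::.nodeDepths(chronTrue)
  estAges <- bathydiv:::.nodeDepths(out)
  H <- max(trueAges)
  expect_lt(max(abs((H - trueAges) - (H - estAges))) / 2, 1e-4)
  expect_equal(rootAge(out), 2, tolerance = 1e-9)
})

test_that("NPRS ages are invariant to rescaling all substitution lengths", {
  chronTrue <- bathydiv:::.treeFromAges(c(3, 1.6, 0.9, 0.4))
  phy <- chronTrue
  set.seed(5)
  phy$edge.length <- phy$edge.length * 0.04 * exp(rnorm(nrow(phy$edge), 0, 0.3))
  cons <- list(list(taxa = "root", min = 3, max = 3))
  a1 <- bathydiv:::.nodeDepths(nprsSmooth(phy, cons, restarts = 5, seed = 2))
  phy2 <- phy
  phy2$edge.length <- phy2$edge.length * 2
  a2 <- bathydiv:::.nodeDepths(nprsSmooth(phy2, cons, restarts = 5, seed = 2))
  expect_lt(max(abs(a1 - a2)), 1e-3)
})

test_that("the NPRS optimum beats a dense grid over node ages", {
  # 5 tips, one rate-shifted clade
  phy <- parseNewick(
    "(((A:0.30,B:0.30):0.10,C:0.12):0.06,(D:0.08,E:0.08):0.10);", "subst")
  cons <- list(list(taxa = "root", min = 1, max = 1))
  out <- nprsSmooth(phy, cons, restarts = 8, seed = 3)
  objFn <- function(ages) {
    # recompute the objective for a candidate age assignment
    test <- phy
    test$edge.length <- ages[test$edge[, 1]] - ages[test$edge[, 2]]
    rate <- phy$edge.length / test$edge.length
    obj <- 0
    parentEdge <- match(phy$edge[, 1], phy$edge[, 2])
    for (e in seq_len(nrow(phy$edge))) {
      pe <- parentEdge[e]
      if (!is.na(pe)) obj <- obj + (rate[pe] - rate[e])^2
    }
    rootKids <- which(is.na(parentEdge))
    obj + sum((rate[rootKids] - mean(rate[rootKids]))^2)
  }
  estAges <- bathydiv:::.nodeDepths(out)
  n <- length(phy$tip.label)
  agesOf <- function(depths) {
    a <- numeric(n + phy$Nnode)
    a[(n + 1):(n + phy$Nnode)] <- depths
    a
  }
  est <- 1 - estAges                      # node ages (tips at 0, root 1)
  bestGrid <- Inf
  for (x2 in seq(0.05, 0.95, by = 0.05)) for (x3 in seq(0.05, 0.95, by = 0.05))
    for (x4 in seq(0.05, 0.95, by = 0.05)) {
      ages <- c(rep(0, n), 1, x2 * 1, x3 * x2, x4 * 1)
      o <- tryCatch(objFn(ages), error = function(e) Inf)
      if (!is.na(o) && o < bestGrid) bestGrid <- o
    }
  expect_lte(attr(out, "objective"), bestGrid + 1e-8)
})

test_that("NPRS enforces constraints and rejects infeasible ones", {
  phy <- bathydiv:::.treeFromAges(c(2, 1, 0.4))
  phy$edge.length <- phy$edge.length * 0.05
  expect_error(nprsSmooth(phy, list(), restarts = 2), "root")
  expect_error(nprsSmooth(phy, list(list(taxa = "root", min = 3, max = 2)),
                          restarts = 2), "infeasible")
  out <- nprsSmooth(phy, list(list(taxa = "root", min = 1.5, max = 2.5)),
                    restarts = 4, seed = 6)
  expect_gte(rootAge(out), 1.5 - 1e-9)
  expect_lte(rootAge(out), 2.5 + 1e-9)
  expect_lte(attr(out, "constraintCheck"), 1e-6)
})
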