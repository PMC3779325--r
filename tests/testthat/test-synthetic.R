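test_that("simulators are reproducible under a fixed seed", {
  cfg <- simConfig(crownAge = 40, nTip = 20, lambda = 0.06, mu = 0.01)
  expect_identical(writeNewick(simulateTree(cfg, seed = 3)),
                   writeNewick(simulateTree(cfg, seed = 3)))
  p <- bisseParams(0.03, 0.09, 0, 0, 0.02, 0.02)
  s1 <- simulateBisseTree(p, nTip = 15, seed = 4)
  s2 <- simulateBisseTree(p, nTip = 15, seed = 4)
  expect_identical(writeNewick(s1$tree), writeNewick(s2$tree))
  expect_identical(s1$states, s2$states)
  expect_identical(musselPreset(9)$traits, musselPreset(9)$traits)
})

test_that("conditioning targets are met exactly", {
  for (cfg in list(simConfig(crownAge = 40, nTip = 12, lambda = 0.06),
                   simConfig(crownAge = 60, nTip = 15, lambda = 0.08, mu = 0.02),
                   simConfig(crownAge = 50, nTip = 10, lambda = 0.09, mu = 0.01,
                             events = data.frame(age = 20, rho = 0.7)),
                   simConfig(crownAge = 85, nTip = 30,
                             lambda = c(0.01, 0.17, 0.05),
                             shiftAges = c(41.2, 33.8)))) {
    tr <- simulateTree(cfg, seed = 11)
    expect_equal(length(tr$tip.label), cfg$nTip)
    expect_equal(rootAge(tr), cfg$crownAge, tolerance = 1e-12)
    expect_s3_class(tr, "chronogram")
  }
})

test_that("a zero speciation rate yields exactly the two crown lineages", {
  tr <- simulateTree(simConfig(crownAge = 40, lambda = 0), seed = 2)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(rootAge(tr), 40)
})

test_that("tip subsampling retains round(n(1-f)) tips uniformly", {
  tr <- randomYuleTree(100, T = 40, lambda = 0.06, seed = 5)
  expect_identical(subsampleTips(tr, 0), tr)
  expect_equal(length(subsampleTips(tr, 0.25, seed = 1)$tip.label), 75L)
  expect_error(subsampleTips(tr, 0.99), "fewer than 3")

  small <- randomYuleTree(10, seed = 6)
  counts <- table(factor(unlist(
    lapply(1:1000, function(i) subsampleTips(small, 0.3, seed = i)$tip.label)),
    levels = small$tip.label))
  # each tip kept with frequency ~0.7
  chi <- sum((counts - 700)^2 / (700 * 0.3))
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.001)
})

test_that("discrete-trait simulation follows the Markov chain", {
  tr <- randomYuleTree(20, seed = 7)
  Q0 <- matrix(0, 2, 2)
  expect_true(all(simulateDiscreteTrait(tr, Q0, rootProbs = c(0, 1),
                                        seed = 1) == 2))
  # high symmetric rate on a deep tree: stationary 50/50
  Q <- matrix(c(-1, 1, 1, -1), 2)
  states <- unlist(lapply(1:40, function(i)
    simulateDiscreteTrait(tr, Q, seed = i)))
  expect_gt(mean(states == 1), 0.45)
  expect_lt(mean(states == 1), 0.55)
})

test_that("Brownian simulation obeys the variance and covariance laws", {
  expect_true(all(simulateContinuousTrait(randomYuleTree(10, seed = 1), 0,
                                          rootValue = 3) == 3))
  tr <- parseNewick("(A:6,B:6);")
  vals <- vapply(1:800, function(i)
    simulateContinuousTrait(tr, 0.5, seed = i), numeric(2))
  expect_equal(var(vals[1, ]), 0.5 * 6, tolerance = 0.15)
  tr2 <- parseNewick("((A:2,B:2):4,C:6);")
  vals2 <- vapply(1:800, function(i)
    simulateContinuousTrait(tr2, 0.5, seed = i), numeric(3))
  expect_equal(cov(vals2[1, ], vals2[2, ]), 0.5 * 4, tolerance = 0.3)
  expect_lt(abs(cov(vals2[1, ], vals2[3, ])), 0.3)
})

test_that("BiSSE simulation reduces to a neutral Yule process when rates are state-independent", {
  p <- bisseParams(0.1, 0.1, 0, 0, 0.05, 0.05)
  sims <- lapply(1:150, function(i) simulateBisseTree(p, nTip = 15, seed = i))
  states <- unlist(lapply(sims, `[[`, "states"))
  expect_gt(mean(states), 0.40)
  expect_lt(mean(states), 0.60)
  # pooled branching times match taxon-conditioned Yule simulations
  btBisse <- unlist(lapply(sims, function(s) branchingTimes(s$tree)))
  btYule <- unlist(lapply(1:150, function(i) {
    set.seed(1000 + i)
    bathydiv:::.simulateNullBt(15, NA, 0.1, 0, "taxa")
  }))
  expect_gt(suppressWarnings(stats::ks.test(btBisse, btYule)$p.value), 0.01)
  # mu = 0: nothing is pruned, tip count equals target exactly
  expect_true(all(vapply(sims, function(s) length(s$tree$tip.label), 1L) == 15L))
})

test_that("the mussel-like preset has the advertised structure", {
  pre <- getPreset()
  expect_equal(length(pre$tree$tip.label), 62L)
  expect_equal(rootAge(pre$tree), 85, tolerance = 1e-9)
  expect_silent(validateTraitTable(pre$traits))
  expect_equal(sum(!is.na(pre$traits$shell_length_mm)), 48L)
  expect_equal(sum(!is.na(pre$traits$methanotroph)), 36L)
  expect_equal(sum(!is.na(pre$traits$symbiont_location)), 24L)
  expect_equal(pre$truth$lambda, c(0.01, 0.17, 0.05))

  # the burst is visible: median per-lineage event rate inside the
  # 41.2-33.8 Ma window exceeds twice the post-burst rate over replicates
  lamAt <- function(bt, lo, hi) {
    cuts <- sort(unique(c(lo, hi, bt[bt > lo & bt < hi])))
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    N <- vapply(mids, function(a) 1 + sum(bt >= a), numeric(1))
    sum(bt[-1] > lo & bt[-1] <= hi) / sum(N * diff(cuts))
  }
  ratio <- vapply(1:25, function(i) {
    bt <- branchingTimes(musselPreset(3000 + i)$tree)
    lamAt(bt, 33.8, 41.2) / max(lamAt(bt, 0, 33.8), 1e-9)
  }, numeric(1))
  expect_gt(median(ratio), 2)
})
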