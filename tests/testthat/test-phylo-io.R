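test_that("Newick parsing validates structure and captures support values", {
  tr <- parseNewick("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(tr$edge.length, c(1, 1))

  tr3 <- parseNewick("((A:1,B:1)0.99:1,C:2);")
  expect_equal(length(tr3$tip.label), 3L)
  expect_true(0.99 %in% nodeSupport(tr3))

  expect_error(parseNewick("((A:1,B:1:1,C:2);"), "unclosed")
  expect_error(parseNewick("(A:1,B:1))((;"), "position")
  expect_error(parseNewick("(A:1,A:1);"), "duplicate")
  expect_error(parseNewick("(A,B);"), "branch length")
})

test_that("parse -> write -> parse round-trip preserves the tree", {
  for (seed in 1:4) {
    tr <- randomYuleTree(8, seed = seed)
    tr2 <- parseNewick(writeNewick(tr))
    expect_setequal(tr2$tip.label, tr$tip.label)
    expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE,
                                     tolerance = 1e-9))
    expect_equal(sort(as.numeric(branchingTimes(tr2))),
                 sort(as.numeric(branchingTimes(tr))), tolerance = 1e-9)
  }
})

test_that("branching times read off node ages, crown first, with validation", {
  bt <- branchingTimes(toyTree3())
  expect_equal(as.numeric(bt), c(2, 1))
  expect_equal(attr(bt, "n"), 3L)

  expect_error(branchingTimes(parseNewick("((A:1,B:2):1,C:2);")),
               "not ultrametric")

  # exact recovery of known node ages
  tr <- bathydiv:::.treeFromAges(c(10, 4, 2.5, 1))
  expect_equal(as.numeric(branchingTimes(tr)), c(10, 4, 2.5, 1))

  for (n in c(5, 20)) {
    expect_length(branchingTimes(randomYuleTree(n, seed = n)), n - 1)
  }
})

test_that("LTT curves start at 2, end at the tip count, and are monotone", {
  ltt <- lttCurve(toyTree3())
  expect_equal(ltt$lineages, c(2, 3, 3))
  expect_equal(ltt$age[1], 2)

  tr <- randomYuleTree(100, T = 40, lambda = 0.06, seed = 8)
  ltt <- lttCurve(tr)
  expect_equal(nrow(ltt), 100)          # 99 branching steps + the present
  expect_true(all(diff(ltt$lineages) >= 0))
  expect_equal(ltt$lineages[nrow(ltt)], 100)
})

test_that("prepareTree collapses weak nodes, prunes missing data, keeps depth", {
  tr <- parseNewick("(((A:1,B:1)0.50:1,C:2)0.97:1,D:3);")
  out <- prepareTree(tr, supportThreshold = 0.95)
  expect_false(ape::is.binary.phylo(out$tree))
  expect_equal(out$tree$Nnode, 2L)       # one node collapsed to a polytomy
  expect_equal(max(bathydiv:::.nodeDepths(out$tree)[1:4]), 3)

  out0 <- prepareTree(tr, supportThreshold = 0)
  expect_equal(out0$tree$edge, tr$edge)

  pre <- getPreset()
  res <- prepareTree(pre$tree, pre$traits, character = "methanotroph")
  expect_equal(length(res$tree$tip.label), 36L)
  expect_equal(nrow(res$traits), 36L)
  expect_identical(res$traits$species, res$tree$tip.label)
  expect_lte(length(res$tree$tip.label), length(pre$tree$tip.label))
  expect_equal(rootAge(res$tree), rootAge(pre$tree), tolerance = 1e-9)

  bad <- pre$traits
  bad$methanotroph <- NA
  bad$methanotroph[1:2] <- 1
  expect_error(prepareTree(pre$tree, bad, character = "methanotroph"),
               "fewer than 3")
})

test_that("trait tables validate and round-trip through TSV", {
  pre <- getPreset()
  f <- tempfile(fileext = ".tsv")
  writeTraitTable(pre$traits, f)
  back <- readTraitTable(f)
  expect_equal(back$species, pre$traits$species)
  expect_equal(back$shell_length_mm, pre$traits$shell_length_mm)

  bad <- pre$traits; bad$habitat[1] <- "lake"
  expect_error(validateTraitTable(bad), "habitat")
  bad <- pre$traits; bad$depth_min_m[1] <- 9000
  expect_error(validateTraitTable(bad), "depth")
  bad <- pre$traits; bad$species[2] <- bad$species[1]
  expect_error(validateTraitTable(bad), "duplicate")
})
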