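#' Brownian-motion ancestral reconstruction of a continuous trait
#'
#' Maximum-likelihood Brownian rate and generalized-least-squares ancestral
#' means (with conditional variances) on a fixed chronogram. Shell lengths
#' should be supplied on the natural-log scale (log of mm).
#'
#' @param phy A chronogram.
#' @param values Named numeric vector keyed by tip label (complete cases
#'   only; prune first with [prepareTree()]).
#' @return An `"asrResult"`-like list: `rootMean`, `sigma2` (per Myr),
#'   `ancestralMeans`, `ancestralVars` (keyed by ape node id), `lnL`.
#' @export
bmAsr <- function(phy, values) {
  n <- length(phy$tip.label)
  stopifnot(n >= 3)
  values <- values[phy$tip.label]
  if (anyNA(values)) stop("missing trait values: prune before reconstruction")
  C <- ape::vcv(phy)
  ch <- chol(C)
  solveC <- function(x) backsolve(ch, backsolve(ch, x, transpose = TRUE))
  one <- rep(1, n)
  Ci1 <- solveC(one)
  mu <- sum(Ci1 * values) / sum(Ci1 * one)
  resid <- values - mu
  Cir <- solveC(resid)
  sigma2 <- sum(resid * Cir) / n
  lnL <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) +
                   sum(resid * Cir) / sigma2)
  # conditional mean/variance of each internal node given the tips
  phy2 <- ape::reorder.phylo(phy, "cladewise")
  depth <- .nodeDepths(phy2)
  H <- max(depth[seq_len(n)])
  nodes <- (n + 1L):(n + phy2$Nnode)
  anc <- setNames(numeric(length(nodes)), nodes)
  avar <- setNames(numeric(length(nodes)), nodes)
  desc <- .descendantTips(phy2)
  for (j in seq_along(nodes)) {
    nd <- nodes[j]
    # covariance of node with each tip = depth of their MRCA; for tips below
    # nd this is the node's own depth, otherwise the MRCA depth with nd
    cv <- vapply(seq_len(n), function(tip) {
      m <- .mrcaDepthCached(phy2, depth, desc, nd, tip)
      m
    }, numeric(1))
    w <- solveC(cv)
    anc[j] <- mu + sum(w * resid)
    avar[j] <- sigma2 * (depth[nd] - sum(w * cv))
  }
  structure(list(rootMean = mu, sigma2 = sigma2,
                 ancestralMeans = anc, ancestralVars = pmax(avar, 0),
                 lnL = lnL, n = n),
            class = "bmAsrResult")
}

.descendantTips <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

# depth (time from root) of the MRCA of an internal node and a tip
.mrcaDepthCached <- function(phy, depth, desc, nd, tip) {
  if (tip %in% desc[[nd]]) return(depth[nd])
  # walk rootward from nd until the tip is below
  n <- length(phy$tip.label)
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  p <- nd
  while (p != n + 1L && !(tip %in% desc[[p]])) p <- parent[p]
  depth[p]
}

#' @export
print.bmAsrResult <- function(x, ...) {
  cat(sprintf("Brownian ancestral reconstruction: root mean = %.4f, sigma^2 = %.5f/Myr, lnL = %.3f\n",
              x$rootMean, x$sigma2, x$lnL))
  invisible(x)
}

#' Discretize a depth range into 500-m bins
#'
#' Half-open bins `[0, 500), [500, 1000), ...`; a range occupies every bin
#' it intersects, and a species whose range spans several bins is coded as
#' multistate (ambiguity over the occupied bins).
#'
#' @param depthMin,depthMax Range limits in metres (`0 <= min <= max`).
#' @param binWidth Bin width in metres (default 500).
#' @param globalMax Optional global maximum depth; when given, the final bin
#'   is closed at `globalMax` and the bin count is reported.
#' @return Integer vector of occupied (1-based) bin indices, with attribute
#'   `nBins` when `globalMax` is given.
#' @export
#' @examples
#' discretizeDepth(300, 1200)  # bins 1, 2, 3
discretizeDepth <- function(depthMin, depthMax, binWidth = 500,
                            globalMax = NULL) {
  stopifnot(depthMin >= 0, depthMax >= depthMin, binWidth > 0)
  lo <- floor(depthMin / binWidth) + 1L
  hi <- floor(depthMax / binWidth) + 1L
  if (depthMax > depthMin && depthMax %% binWidth == 0)
    hi <- hi - 1L                        # half-open: max on a boundary
  bins <- seq.int(lo, max(lo, hi))
  if (!is.null(globalMax)) {
    nBins <- ceiling(globalMax / binWidth)
    bins <- bins[bins <= nBins]          # final bin closed at globalMax
    attr(bins, "nBins") <- as.integer(nBins)
  }
  bins
}

#' Depth-bin state sets for a trait table
#'
#' @param traits A trait table (see [readTraitTable()]).
#' @param binWidth Bin width in metres.
#' @return Named list of occupied-bin sets (NULL for species without depth
#'   data), with attribute `nBins` spanning the table.
#' @export
depthStateSets <- function(traits, binWidth = 500) {
  gmax <- max(traits$depth_max_m, na.rm = TRUE)
  out <- lapply(seq_len(nrow(traits)), function(i) {
    if (is.na(traits$depth_min_m[i]) || is.na(traits$depth_max_m[i])) return(NULL)
    as.integer(discretizeDepth(traits$depth_min_m[i], traits$depth_max_m[i],
                               binWidth, globalMax = gmax))
  })
  names(out) <- traits$species
  attr(out, "nBins") <- as.integer(ceiling(gmax / binWidth))
  out
}

# ---- Pagel's correlation test ----------------------------------------------

# joint 4-state space over two binary traits, ordered (x, y):
# 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1)
.pagelQ <- function(rates, dependent) {
  Q <- matrix(0, 4, 4)
  if (!dependent) {
    # rates = (ax01, ax10, by01, by10): x and y evolve independently
    a01 <- rates[1]; a10 <- rates[2]; b01 <- rates[3]; b10 <- rates[4]
    Q[1, 3] <- a01; Q[2, 4] <- a01; Q[3, 1] <- a10; Q[4, 2] <- a10
    Q[1, 2] <- b01; Q[3, 4] <- b01; Q[2, 1] <- b10; Q[4, 3] <- b10
  } else {
    # 8 rates: each single-trait change conditioned on the other trait
    Q[1, 3] <- rates[1]; Q[2, 4] <- rates[2]   # x 0->1 | y=0, y=1
    Q[3, 1] <- rates[3]; Q[4, 2] <- rates[4]   # x 1->0 | y=0, y=1
    Q[1, 2] <- rates[5]; Q[3, 4] <- rates[6]   # y 0->1 | x=0, x=1
    Q[2, 1] <- rates[7]; Q[4, 3] <- rates[8]   # y 1->0 | x=0, x=1
  }
  diag(Q) <- -rowSums(Q)
  Q
}

.pagelFit <- function(po, nTip, tipL, dependent, start, restarts,
                      control = list(factr = 1e6, maxit = 500)) {
  nll <- function(p) pagel_nll_cpp(p, dependent, po$edge, po$len, nTip, tipL)
  best <- NULL
  for (s in seq_len(max(1L, restarts))) {
    p0 <- if (s == 1) start else start + rnorm(length(start), 0, 0.7)
    o <- tryCatch(stats::optim(p0, nll, method = "L-BFGS-B", lower = -18,
                               upper = 8, control = control),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimiser restarts failed")
  best
}

#' Pagel's test of correlated evolution of two binary characters
#'
#' Compares the 4-rate model in which two binary traits evolve
#' independently against the 8-rate model in which each trait's transition
#' rates depend on the state of the other. The statistic is
#' `dlogL = lnL(dependent) - lnL(independent)`; its null distribution is
#' built by Monte-Carlo simulation under the fitted independent model, with
#' both models refitted to every simulated pair.
#'
#' @param phy A chronogram.
#' @param x,y Named binary (0/1) vectors; species with missing values in
#'   either trait are pruned.
#' @param restarts Optimiser restarts for the observed-data fits (the
#'   simulation refits reuse the observed fits as warm starts).
#' @param sims Monte-Carlo replicates.
#' @param seed Optional seed.
#' @return A `"pagelTest"`: `dlogL`, `lnLIndependent`, `lnLDependent`,
#'   Monte-Carlo `p.value`, `nSpecies`, fitted rate matrices.
#' @export
pagelTest <- function(phy, x, y, restarts = 10, sims = 1000, seed = NULL) {
  common <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  common <- intersect(common, phy$tip.label)
  if (length(common) < length(phy$tip.label))
    phy <- ape::drop.tip(phy, setdiff(phy$tip.label, common))
  x <- x[phy$tip.label]; y <- y[phy$tip.label]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("degenerate (constant) trait: Pagel's test needs both states observed")
  n <- length(phy$tip.label)
  # mapping: (0,0)=1 (0,1)=2 (1,0)=3 (1,1)=4
  joint <- stats::setNames(1L + as.integer(y) + 2L * as.integer(x),
                           phy$tip.label)
  tipL <- matrix(0, n, 4)
  tipL[cbind(seq_len(n), joint)] <- 1
  po <- .postorderEdges(phy)
  depth <- max(.nodeDepths(phy))
  start <- log(rep(1 / depth, 4))
  oI <- .pagelFit(po, n, tipL, FALSE, start, restarts)
  oD <- .pagelFit(po, n, tipL, TRUE,
                  oI$par[c(1, 1, 2, 2, 3, 3, 4, 4)], restarts)
  if (oD$value > oI$value) oD$value <- oI$value
  obs <- oI$value - oD$value             # = dlogL >= 0
  ratesI <- exp(oI$par)                  # (x01, x10, y01, y10)
  Qx <- matrix(c(-ratesI[1], ratesI[1], ratesI[2], -ratesI[2]), 2,
               byrow = TRUE)
  Qy <- matrix(c(-ratesI[3], ratesI[3], ratesI[4], -ratesI[4]), 2,
               byrow = TRUE)
  .withSeed(seed, {
    simCtl <- list(factr = 1e10, pgtol = 5e-4, maxit = 200)
    nullStats <- vapply(seq_len(sims), function(i) {
      xs <- simulateDiscreteTrait(phy, Qx) - 1L
      ys <- simulateDiscreteTrait(phy, Qy) - 1L
      js <- 1L + as.integer(ys) + 2L * as.integer(xs)
      tL <- matrix(0, n, 4)
      tL[cbind(seq_len(n), js)] <- 1
      sI <- .pagelFit(po, n, tL, FALSE, oI$par, 1, control = simCtl)
      sD <- .pagelFit(po, n, tL, TRUE,
                      sI$par[c(1, 1, 2, 2, 3, 3, 4, 4)], 1, control = simCtl)
      max(sI$value - sD$value, 0)
    }, numeric(1))
    p <- (1 + sum(nullStats >= obs)) / (1 + sims)
    structure(list(dlogL = obs, lnLIndependent = -oI$value,
                   lnLDependent = -oD$value, p.value = p, sims = sims,
                   nSpecies = n, ratesIndependent = ratesI,
                   ratesDependent = exp(oD$par), null = nullStats),
              class = "pagelTest")
  })
}

#' @export
print.pagelTest <- function(x, ...) {
  cat(sprintf(
    "Pagel's test (%d species): dlogL = %.3f, Monte-Carlo p = %.4g (%d sims)\n",
    x$nSpecies, x$dlogL, x$p.value, x$sims))
  invisible(x)
}

# ---- phylogenetic ANOVA ----------------------------------------------------

#' Phylogenetic analysis of variance
#'
#' Ordinary ANOVA F statistic for a continuous trait across groups, with a
#' null F distribution generated by simulating Brownian motion along the
#' tree (rate estimated from the data), giving the "phylogenetic p-value"
#' alongside the parametric one.
#'
#' @param phy A chronogram.
#' @param y Named continuous trait.
#' @param groups Named group factor; species missing either variable are
#'   pruned.
#' @param sims Brownian simulations (default 5000).
#' @param seed Optional seed.
#' @return A `"phyloAnova"`: `F`, `df`, parametric `p.parametric`,
#'   simulation-based `p.phylo`, `sigma2`, `nSpecies`.
#' @export
phyloAnova <- function(phy, y, groups, sims = 5000, seed = NULL) {
  common <- intersect(names(y)[!is.na(y)], names(groups)[!is.na(groups)])
  common <- intersect(common, phy$tip.label)
  if (length(common) < length(phy$tip.label))
    phy <- ape::drop.tip(phy, setdiff(phy$tip.label, common))
  y <- y[phy$tip.label]
  g <- factor(unlist(groups[phy$tip.label]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("singleton group(s): ",
                              paste(names(which(table(g) < 2)), collapse = ", "))
  n <- length(y)
  Fstat <- function(v) {
    fit <- stats::lm(v ~ g)
    unname(summary(fit)$fstatistic[1])
  }
  Fobs <- Fstat(y)
  df1 <- nlevels(g) - 1L; df2 <- n - nlevels(g)
  sigma2 <- bmAsrSigma2(phy, y)
  C <- ape::vcv(phy)
  ch <- chol(C)
  .withSeed(seed, {
    Fnull <- vapply(seq_len(sims), function(i) {
      v <- as.vector(t(ch) %*% rnorm(n, 0, sqrt(sigma2)))
      names(v) <- rownames(C)
      Fstat(v[phy$tip.label])
    }, numeric(1))
    structure(list(F = unname(Fobs), df = c(df1, df2),
                   p.parametric = stats::pf(Fobs, df1, df2, lower.tail = FALSE),
                   p.phylo = (1 + sum(Fnull >= Fobs)) / (1 + sims),
                   sigma2 = sigma2, sims = sims, nSpecies = n),
              class = "phyloAnova")
  })
}

# ML Brownian rate only (cheap helper shared with the ANOVA null)
bmAsrSigma2 <- function(phy, values) {
  n <- length(phy$tip.label)
  values <- values[phy$tip.label]
  C <- ape::vcv(phy)
  ch <- chol(C)
  solveC <- function(x) backsolve(ch, backsolve(ch, x, transpose = TRUE))
  one <- rep(1, n)
  Ci1 <- solveC(one)
  mu <- sum(Ci1 * values) / sum(Ci1 * one)
  resid <- values - mu
  sum(resid * solveC(resid)) / n
}

#' @export
print.phyloAnova <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ANOVA (%d species): F = %.3f (d.f. %d, %d), parametric p = %.4g, phylogenetic p = %.4g\n",
    x$nSpecies, x$F, x$df[1], x$df[2], x$p.parametric, x$p.phylo))
  invisible(x)
}

# ---- PGLS -------------------------------------------------------------------

#' Phylogenetic generalized least squares regression
#'
#' GLS regression of `y` on `x` with Brownian error covariance (shared path
#' lengths); on a star phylogeny this reduces exactly to ordinary least
#' squares. Reports intercept and slope t statistics, the overall F for the
#' slope, and residual degrees of freedom.
#'
#' @param phy A chronogram.
#' @param y,x Named continuous vectors; incomplete species are pruned.
#' @return A `"pglsFit"`: `coefficients`, `se`, `t`, `p.t`, `F`, `df`,
#'   `p.F`, `sigma2`, `nSpecies`.
#' @export
pglsFit <- function(phy, y, x) {
  common <- intersect(names(y)[!is.na(y)], names(x)[!is.na(x)])
  common <- intersect(common, phy$tip.label)
  if (length(common) < 4) stop("fewer than 4 complete cases")
  if (length(common) < length(phy$tip.label))
    phy <- ape::drop.tip(phy, setdiff(phy$tip.label, common))
  y <- y[phy$tip.label]; x <- x[phy$tip.label]
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x = x)
  C <- ape::vcv(phy)
  ch <- chol(C)
  w <- function(M) backsolve(ch, M, transpose = TRUE)  # whitening
  Xw <- w(X); yw <- w(y)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) stop("singular design (constant predictor?)")
  beta <- solve(XtX, crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  vc <- sigma2 * solve(XtX)
  se <- sqrt(diag(vc))
  tstat <- stats::setNames(beta[, 1] / se, c("(Intercept)", "x"))
  pt2 <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  Fstat <- tstat[["x"]]^2
  structure(list(coefficients = beta[, 1], se = se, t = tstat, p.t = pt2,
                 F = unname(Fstat), df = c(1L, df),
                 p.F = stats::pf(Fstat, 1, df, lower.tail = FALSE),
                 sigma2 = sigma2, nSpecies = n),
            class = "pglsFit")
}

#' @export
print.pglsFit <- function(x, ...) {
  cat(sprintf(
    paste0("PGLS (%d species): intercept t = %.3f (p = %.3g), slope t = %.3f ",
           "(p = %.3g), F = %.3f (d.f. 1, %d, p = %.3g)\n"),
    x$nSpecies, x$t[1], x$p.t[1], x$t[2], x$p.t[2], x$F, x$df[2], x$p.F))
  invisible(x)
}

# ---- depth comparison -------------------------------------------------------

#' Mann-Whitney comparison of depths between habitat groups
#'
#' Wilcoxon rank-sum test of species depths (midpoint of the depth range by
#' default) between two habitat groups, e.g. vent/seep versus organic-fall
#' species; exact p for small samples, normal approximation with tie
#' correction otherwise.
#'
#' @param depths Named numeric vector of depths (m).
#' @param groups Named 2-level factor/character vector.
#' @return A `"TestResult"`-style list: `U`, `p.value`, group sizes.
#' @export
mannWhitneyDepth <- function(depths, groups) {
  common <- intersect(names(depths)[!is.na(depths)],
                      names(groups)[!is.na(groups)])
  d <- depths[common]
  g <- factor(unlist(groups[common]))
  if (nlevels(g) != 2) stop("need exactly 2 non-empty groups")
  if (any(table(g) == 0)) stop("empty group")
  exact <- all(table(g) <= 12) && !anyDuplicated(d)
  wt <- suppressWarnings(stats::wilcox.test(d ~ g, exact = exact))
  structure(list(U = unname(wt$statistic), p.value = wt$p.value,
                 n = as.vector(table(g)), groups = levels(g),
                 exact = exact),
            class = "mannWhitneyDepth")
}

#' @export
print.mannWhitneyDepth <- function(x, ...) {
  cat(sprintf("Mann-Whitney depth test (%s: n = %d vs %s: n = %d): U = %g, p = %.4g\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2], x$U, x$p.value))
  invisible(x)
}
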