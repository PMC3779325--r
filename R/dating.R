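#' Soft maximum of an offset-exponential fossil calibration
#'
#' Fossil calibrations modelled as an exponential prior above a hard
#' minimum age hold a small prior tail probability above a "soft maximum";
#' here that bound is the 0.95 quantile by convention:
#' `offset + mean * (-log(1 - quantile))`.
#'
#' @param offset Hard minimum bound (Myr, > 0).
#' @param mean Mean of the exponential part (Myr, > 0).
#' @param quantile Tail quantile defining the soft bound (default 0.95).
#' @return Age in Myr.
#' @export
#' @examples
#' calibrationSoftBound(45, 1.2)    # 48.6 Myr
#' calibrationSoftBound(25.2, 0.7)  # 27.3 Myr
calibrationSoftBound <- function(offset, mean, quantile = 0.95) {
  stopifnot(offset > 0, mean > 0)
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  offset - mean * log(1 - quantile)
}

#' @rdname calibrationSoftBound
#' @param age Age(s) at which to evaluate.
#' @export
calibrationPriorDensity <- function(age, offset, mean) {
  stopifnot(offset > 0, mean > 0)
  ifelse(age < offset, 0, exp(-(age - offset) / mean) / mean)
}

#' @rdname calibrationSoftBound
#' @export
calibrationPriorCDF <- function(age, offset, mean) {
  stopifnot(offset > 0, mean > 0)
  ifelse(age < offset, 0, 1 - exp(-(age - offset) / mean))
}

#' Nonparametric rate smoothing (NPRS) dating
#'
#' Estimates node ages from a phylogram (branch lengths in
#' substitutions/site) by minimising the sum over ancestor-descendant branch
#' pairs of squared local-rate differences (local rate = substitution length
#' / time duration), plus a root term penalising the variance of the root
#' children's rates. Ages are parameterised as proportions of the parent age
#' through a logistic transform, which enforces parent > child ordering
#' structurally; the root age is fixed or bounded by a constraint, and
#' further min/max constraints are handled by penalty with post-hoc
#' verification.
#'
#' @param phy Phylogram (`"phylo"`, lengths in substitutions/site).
#' @param constraints List of constraints, each a list with `taxa`
#'   (character vector, the constrained node is their MRCA; `"root"` is
#'   shorthand for the root) and `min` and/or `max` ages (equal for a fixed
#'   age). At least the root must be bounded.
#' @param restarts Optimisation restarts from jittered starting points.
#' @param seed Optional seed for the restart jitter.
#' @param rootTerm Also penalise the variance of the root children's local
#'   rates (default TRUE).
#' @return A chronogram; attributes `objective`, `convergence`, `restarts`,
#'   and `constraintCheck` (max violation).
#' @export
nprsSmooth <- function(phy, constraints, restarts = 10, seed = NULL,
                       rootTerm = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  root <- n + 1L
  cons <- lapply(constraints, function(cc) {
    node <- if (identical(cc$taxa, "root") || length(cc$taxa) == n) root
            else ape::getMRCA(phy, cc$taxa)
    list(node = node, min = cc$min %||% NA_real_, max = cc$max %||% NA_real_)
  })
  rootCons <- Filter(function(cc) cc$node == root, cons)
  if (!length(rootCons))
    stop("the root age must be fixed or bounded by a constraint")
  rmin <- max(vapply(rootCons, function(cc) cc$min %||% NA_real_, numeric(1)),
              na.rm = TRUE)
  rmax <- min(vapply(rootCons, function(cc) cc$max %||% NA_real_, numeric(1)),
              na.rm = TRUE)
  if (!is.finite(rmin) && !is.finite(rmax))
    stop("root constraint must include a finite min or max")
  if (!is.finite(rmin)) rmin <- rmax / 10
  if (!is.finite(rmax)) rmax <- rmin * 10
  if (rmin > rmax) stop("infeasible root constraint (min > max)")
  otherCons <- Filter(function(cc) cc$node != root, cons)

  phy2 <- ape::reorder.phylo(phy, "cladewise")
  edge <- phy2$edge; elen <- phy2$edge.length
  parent <- integer(nn); parent[edge[, 2]] <- edge[, 1]
  plen <- numeric(nn); plen[edge[, 2]] <- elen
  internals <- setdiff(unique(edge[, 1]), root)   # non-root internal nodes
  ord <- order(.nodeDepths(phy2)[c(root, internals)])  # root-first
  intSeq <- c(root, internals)[ord]
  childrenOf <- split(edge[, 2], edge[, 1])

  rootFixed <- abs(rmax - rmin) < 1e-12
  nPar <- length(internals) + if (rootFixed) 0L else 1L
  agesFrom <- function(p) {
    ages <- numeric(nn)                   # tips at 0
    i <- 0L
    for (nd in intSeq) {
      if (nd == root) {
        if (rootFixed) ages[nd] <- rmin
        else {
          i <- i + 1L
          ages[nd] <- rmin + (rmax - rmin) * stats::plogis(p[i])
        }
      } else {
        i <- i + 1L
        ages[nd] <- ages[parent[nd]] * stats::plogis(p[i])
      }
    }
    ages
  }
  objective <- function(ages) {
    dur <- ages[parent[edge[, 2]]] - ages[edge[, 2]]
    rate <- numeric(nn)
    ok <- dur > 1e-12
    rate[edge[, 2][ok]] <- elen[ok] / dur[ok]
    rate[edge[, 2][!ok]] <- NA_real_       # zero-duration: rate term dropped
    obj <- 0
    for (nd in internals) {
      rp <- rate[nd]
      if (is.na(rp)) next
      for (ch in childrenOf[[as.character(nd)]]) {
        rc <- rate[ch]
        if (!is.na(rc)) obj <- obj + (rp - rc)^2
      }
    }
    if (rootTerm) {
      rc <- rate[childrenOf[[as.character(root)]]]
      rc <- rc[!is.na(rc)]
      if (length(rc) > 1) obj <- obj + sum((rc - mean(rc))^2)
    }
    # penalty for non-root min/max constraints
    pen <- 0
    for (cc in otherCons) {
      if (!is.na(cc$min) && ages[cc$node] < cc$min)
        pen <- pen + (cc$min - ages[cc$node])^2
      if (!is.na(cc$max) && ages[cc$node] > cc$max)
        pen <- pen + (ages[cc$node] - cc$max)^2
    }
    obj + 1e6 * pen
  }
  fn <- function(p) objective(agesFrom(p))
  .withSeed(seed, {
    best <- NULL
    for (s in seq_len(restarts)) {
      p0 <- rnorm(nPar, 0, if (s == 1) 1e-4 else 1)
      o <- tryCatch(stats::optim(p0, fn, method = "BFGS",
                                 control = list(maxit = 2000, reltol = 1e-14)),
                    error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("all NPRS restarts failed")
    ages <- agesFrom(best$par)
    viol <- 0
    for (cc in otherCons) {
      if (!is.na(cc$min)) viol <- max(viol, cc$min - ages[cc$node])
      if (!is.na(cc$max)) viol <- max(viol, ages[cc$node] - cc$max)
    }
    out <- phy2
    out$edge.length <- ages[edge[, 1]] - ages[edge[, 2]]
    out <- asChronogram(out, tol = 1e-6)
    attr(out, "objective") <- objective(ages)
    attr(out, "convergence") <- best$convergence
    attr(out, "restarts") <- restarts
    attr(out, "constraintCheck") <- max(viol, 0)
    out
  })
}
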