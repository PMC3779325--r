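#' Simulation configuration for diversification tree models
#'
#' Bundles and validates the ingredients of a tree simulation: a rate
#' schedule (piecewise-constant speciation/extinction rates over age
#' intervals), optional instantaneous mass-extinction events, conditioning
#' targets, and a sampling fraction.
#'
#' @param crownAge Crown (root) age T in Myr, or `NULL`.
#' @param nTip Target tip count, or `NULL`. At least one of `crownAge`,
#'   `nTip` must be set.
#' @param lambda Speciation rate(s) per Myr: scalar or one per interval.
#' @param mu Extinction rate(s) per Myr, recycled like `lambda`.
#' @param shiftAges Ages (Myr, descending) of rate shifts; `length(lambda)`
#'   must equal `length(shiftAges) + 1`, rates listed from oldest interval to
#'   youngest.
#' @param events Mass-extinction events: data frame with columns `age` (Myr)
#'   and `rho` (survival fraction in (0, 1]); each lineage alive at the event
#'   survives independently with probability `rho`.
#' @param samplingFraction Fraction of extant species sampled, in (0, 1].
#' @param budget Rejection budget for exact conditioning (default `1e5`).
#' @return A validated list of class `"simConfig"`.
#' @export
simConfig <- function(crownAge = NULL, nTip = NULL, lambda = 0.05, mu = 0,
                      shiftAges = numeric(0), events = NULL,
                      samplingFraction = 1, budget = 1e5) {
  if (is.null(crownAge) && is.null(nTip))
    stop("set at least one conditioning target (crownAge and/or nTip)")
  if (!is.null(nTip) && nTip < 2) stop("unattainable conditioning: nTip < 2")
  k <- length(shiftAges) + 1L
  lambda <- rep_len(lambda, k)
  mu <- rep_len(mu, k)
  stopifnot(all(lambda >= 0), all(mu >= 0),
            samplingFraction > 0, samplingFraction <= 1)
  if (anyDuplicated(shiftAges)) stop("shiftAges must be distinct")
  shiftAges <- sort(shiftAges, decreasing = TRUE)
  if (!is.null(crownAge) && length(shiftAges) && any(shiftAges >= crownAge))
    stop("shift ages must lie inside (0, crownAge)")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events), all(c("age", "rho") %in% names(events)),
              all(events$rho > 0), all(events$rho <= 1), all(events$age > 0))
    events <- events[order(events$age, decreasing = TRUE), , drop = FALSE]
  }
  structure(list(crownAge = crownAge, nTip = nTip, lambda = lambda, mu = mu,
                 shiftAges = shiftAges, events = events,
                 samplingFraction = samplingFraction, budget = budget),
            class = "simConfig")
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# piecewise-constant rate lookup by age; intervals from oldest to youngest
.rateAt <- function(age, rates, shiftAges) {
  idx <- findInterval(-age, -c(Inf, shiftAges))  # 1 = oldest interval
  rates[idx]
}

# cumulative speciation intensity Lambda(x) = int_0^x lambda(u) du (age scale)
.cumIntensity <- function(x, lambda, shiftAges) {
  bounds <- c(0, rev(shiftAges), Inf)     # ascending age bounds
  ratesAsc <- rev(lambda)                 # youngest first
  vapply(x, function(a) {
    lo <- bounds[-length(bounds)]
    hi <- pmin(bounds[-1], a)
    sum(pmax(hi - lo, 0) * ratesAsc)
  }, numeric(1))
}

# exact sampler: node ages of a (possibly episodic) pure-birth tree
# conditioned on crown age T and n tips are iid with CDF
# (1 - exp(-Lambda(x))) / (1 - exp(-Lambda(T))) on [0, T]
.samplePureBirthAges <- function(n, T, lambda, shiftAges) {
  if (n == 2) return(numeric(0))
  u <- runif(n - 2)
  FT <- 1 - exp(-.cumIntensity(T, lambda, shiftAges))
  target <- -log(1 - u * FT)              # = Lambda(x)
  # invert the piecewise-linear Lambda
  bounds <- c(0, rev(shiftAges), T)
  ratesAsc <- rev(lambda)
  Lb <- c(0, cumsum(diff(bounds) * ratesAsc[seq_len(length(bounds) - 1)]))
  idx <- findInterval(target, Lb, rightmost.closed = TRUE)
  idx <- pmin(idx, length(bounds) - 1)
  x <- bounds[idx] + (target - Lb[idx]) / ratesAsc[idx]
  pmin(x, T)
}

# exact sampler for a constant-rate birth-death tree conditioned on (T, n):
# node ages iid with density proportional to lambda * p1(x) on [0, T]
.sampleBDAges <- function(n, T, lambda, mu) {
  if (n == 2) return(numeric(0))
  if (mu <= 0) return(.samplePureBirthAges(n, T, lambda, numeric(0)))
  r <- lambda - mu
  if (abs(r) < 1e-12) r <- 1e-12
  G <- function(x) (1 / (lambda - mu) - 1 / (lambda * exp(r * x) - mu))
  u <- runif(n - 2) * G(T)
  # invert G: 1/(lam e^{rx} - mu) = 1/r' ... solve analytically
  inner <- 1 / (1 / (lambda - mu) - u)
  x <- log((inner + mu) / lambda) / r
  pmin(pmax(x, 0), T)
}

# build a chronogram from descending node ages (crown age first) by
# splitting a uniformly chosen extant lineage at each event (exchangeable
# topology, exact for state-independent models)
.treeFromAges <- function(ages, tipPrefix = "t") {
  stopifnot(!is.unsorted(rev(ages)))
  n <- length(ages) + 1L
  if (n < 2) stop("need at least one (crown) age")
  nodeId <- n + seq_len(n - 1L)           # internal ids in age order
  # active lineages: parent node id + birth age
  par <- c(nodeId[1], nodeId[1])
  birth <- c(ages[1], ages[1])
  edges <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  ne <- 0L
  for (j in seq_len(n - 1L)[-1]) {
    i <- sample.int(length(par), 1L)
    ne <- ne + 1L
    edges[ne, ] <- c(par[i], nodeId[j])
    elen[ne] <- birth[i] - ages[j]
    par[i] <- nodeId[j]; birth[i] <- ages[j]
    par <- c(par, nodeId[j]); birth <- c(birth, ages[j])
  }
  for (i in seq_along(par)) {
    ne <- ne + 1L
    edges[ne, ] <- c(par[i], i)
    elen[ne] <- birth[i]
  }
  phy <- list(edge = edges, edge.length = elen,
              tip.label = paste0(tipPrefix, seq_len(n)), Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  asChronogram(phy)
}

# forward Gillespie simulation of a (episodic) birth-death process with
# optional mass-extinction events, from 2 crown lineages over [0, T] forward
# time; returns a lineage table
.simForwardBD <- function(T, lambda, mu, shiftAges, events, maxLineages = 1e5) {
  # forward-time breakpoints where rates change or events strike
  evAge <- if (is.null(events)) numeric(0) else events$age
  evRho <- if (is.null(events)) numeric(0) else events$rho
  brkAges <- sort(unique(c(shiftAges, evAge)), decreasing = TRUE)
  brkFwd <- T - brkAges
  birth <- c(0, 0); parent <- c(NA_integer_, NA_integer_)
  death <- c(NA_real_, NA_real_)          # NA = alive
  alive <- c(TRUE, TRUE)
  t <- 0
  nextBrk <- 1L
  repeat {
    nAlive <- sum(alive)
    if (nAlive == 0L) break
    if (length(birth) > maxLineages)
      stop("simulation exceeded the lineage cap (runaway diversification)")
    age <- T - t
    lam <- .rateAt(age - 1e-12, lambda, shiftAges)
    m <- .rateAt(age - 1e-12, mu, shiftAges)
    tot <- nAlive * (lam + m)
    tNext <- if (tot > 0) t + rexp(1, tot) else Inf
    bound <- if (nextBrk <= length(brkFwd)) brkFwd[nextBrk] else T
    if (tNext >= min(bound, T)) {
      if (bound < T && nextBrk <= length(brkFwd)) {
        t <- bound
        hitAge <- brkAges[nextBrk]
        nextBrk <- nextBrk + 1L
        hit <- which(!is.na(match(evAge, hitAge)))
        if (length(hit)) {                # mass extinction strikes
          rho <- prod(evRho[hit])
          idx <- which(alive)
          die <- idx[runif(length(idx)) > rho]
          death[die] <- t
          alive[die] <- FALSE
        }
        next
      }
      break                               # reached the present
    }
    t <- tNext
    i <- which(alive)[sample.int(nAlive, 1L)]
    if (runif(1) < lam / (lam + m)) {     # speciation: new lineage
      birth <- c(birth, t); parent <- c(parent, i)
      death <- c(death, NA_real_); alive <- c(alive, TRUE)
    } else {
      death[i] <- t; alive[i] <- FALSE
    }
  }
  data.frame(id = seq_along(birth), parent = parent, birth = birth,
             death = ifelse(is.na(death), T, death), alive = alive)
}

# reconstructed (extinct-pruned) tree from a lineage table; returns NULL if
# fewer than 2 of the crown lineages' descendants survive on both sides
.reconstructFromLineages <- function(lin, T, tipState = NULL) {
  kids <- split(lin$id[-(1:2)], lin$parent[-(1:2)])
  surv <- logical(nrow(lin))
  for (i in rev(seq_len(nrow(lin)))) {    # children have larger ids
    ch <- kids[[as.character(i)]]
    surv[i] <- lin$alive[i] || (length(ch) && any(surv[ch]))
  }
  if (!(surv[1] && surv[2])) return(NULL)
  env <- new.env()
  env$edges <- list(); env$tipAge <- numeric(0); env$tipLin <- integer(0)
  # returns nested list (age, left, right) or tip marker
  recon <- function(i, from) {
    ch <- kids[[as.character(i)]]
    ch <- ch[surv[ch] & lin$birth[ch] > from]
    ch <- ch[order(lin$birth[ch])]
    if (!length(ch)) {
      if (!lin$alive[i]) return(NULL)
      return(list(tip = i))
    }
    t1 <- lin$birth[ch[1]]
    left <- recon(i, t1)
    right <- recon(ch[1], t1)
    if (is.null(left)) return(right)
    list(age = T - t1, left = left, right = right)
  }
  tree <- list(age = T, left = recon(1, 0), right = recon(2, 0))
  .nestedToPhylo(tree, tipState = tipState, lin = lin)
}

.nestedToPhylo <- function(tree, tipState = NULL, lin = NULL) {
  nTipOf <- function(nd) if (!is.null(nd$tip)) 1L else nTipOf(nd$left) + nTipOf(nd$right)
  n <- nTipOf(tree)
  env <- new.env()
  env$edge <- matrix(0L, 2L * n - 2L, 2L); env$elen <- numeric(2L * n - 2L)
  env$ne <- 0L; env$tip <- 0L; env$int <- n + 1L
  env$states <- integer(n)
  walk <- function(nd, parentId, parentAge) {
    if (!is.null(nd$tip)) {
      env$tip <- env$tip + 1L
      id <- env$tip
      if (!is.null(tipState)) env$states[id] <- tipState[nd$tip]
      age <- 0
    } else {
      id <- env$int; env$int <- env$int + 1L
      age <- nd$age
    }
    if (!is.na(parentId)) {
      env$ne <- env$ne + 1L
      env$edge[env$ne, ] <- c(parentId, id)
      env$elen[env$ne] <- parentAge - age
    }
    if (is.null(nd$tip)) {
      walk(nd$left, id, age)
      walk(nd$right, id, age)
    }
  }
  walk(tree, NA_integer_, NA_real_)
  phy <- list(edge = env$edge, edge.length = env$elen,
              tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy <- asChronogram(phy, tol = 1e-8)
  if (!is.null(tipState))
    attr(phy, "tipStates") <- stats::setNames(env$states, phy$tip.label)
  phy
}

#' Simulate a reconstructed diversification tree
#'
#' Simulates a tree under the configured birth-death regime (constant,
#' episodic multi-rate, and/or with mass-extinction events), prunes extinct
#' lineages, and returns an ultrametric chronogram. Conditioning is exact:
#' crown age equals `crownAge` to machine precision and, when `nTip` is set,
#' the tip count matches exactly. Pure-birth regimes conditioned on both
#' targets use an exact conditional sampler of node ages; regimes with
#' extinction fall back to rejection with the configured budget.
#'
#' @param config A [simConfig()].
#' @param seed Optional integer seed (reproducible output for equal seeds).
#' @return A chronogram; tips are labelled `t1..tn`.
#' @export
#' @examples
#' tr <- simulateTree(simConfig(crownAge = 40, nTip = 10, lambda = 0.05), seed = 1)
simulateTree <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(seed, .simulateTreeImpl(config))
}

.simulateTreeImpl <- function(config) {
  cf <- config
  pureBirth <- all(cf$mu == 0) && is.null(cf$events)
  if (!is.null(cf$crownAge) && !is.null(cf$nTip) && pureBirth) {
    nTrue <- .inflatedN(cf$nTip, cf$samplingFraction)
    ages <- c(cf$crownAge,
              sort(.samplePureBirthAges(nTrue, cf$crownAge, cf$lambda, cf$shiftAges),
                   decreasing = TRUE))
    phy <- .treeFromAges(ages)
    return(.maybeSubsample(phy, nTrue, cf$nTip))
  }
  if (!is.null(cf$crownAge) && !is.null(cf$nTip) && length(cf$shiftAges) == 0 &&
      cf$lambda[1] > 0) {
    # constant-rate birth-death (with or without mass extinctions): exact
    # conditional node-age sampler
    nTrue <- .inflatedN(cf$nTip, cf$samplingFraction)
    ages <- c(cf$crownAge,
              sort(.sampleMEAges(nTrue, cf$crownAge, cf$lambda, cf$mu,
                                 cf$events), decreasing = TRUE))
    phy <- .treeFromAges(ages)
    return(.maybeSubsample(phy, nTrue, cf$nTip))
  }
  if (is.null(cf$crownAge))
    stop("conditioning on nTip alone is supported only via simulateBisseTree-style growth; set crownAge")
  nTrue <- if (is.null(cf$nTip)) NULL else .inflatedN(cf$nTip, cf$samplingFraction)
  for (try in seq_len(cf$budget)) {
    lin <- .simForwardBD(cf$crownAge, cf$lambda, cf$mu, cf$shiftAges, cf$events)
    phy <- .reconstructFromLineages(lin, cf$crownAge)
    if (is.null(phy)) next
    if (!is.null(nTrue) && length(phy$tip.label) != nTrue) next
    return(.maybeSubsample(phy, length(phy$tip.label), cf$nTip))
  }
  stop("rejection budget (", cf$budget, ") exceeded; conditioning on ",
       "crownAge = ", cf$crownAge,
       if (!is.null(nTrue)) paste0(", nTip = ", nTrue),
       " is too far from the process mean")
}

.inflatedN <- function(nTip, f) {
  if (f >= 1) return(nTip)
  round(nTip / f)
}

.maybeSubsample <- function(phy, nTrue, nTip) {
  if (is.null(nTip) || nTrue == nTip) return(phy)
  subsampleTips(phy, fractionMissing = 1 - nTip / nTrue)
}

#' Randomly subsample tips (incomplete taxon sampling)
#'
#' Retains a uniformly random subset of `round(n * (1 - fractionMissing))`
#' tips and prunes the rest; the result remains an ultrametric chronogram.
#'
#' @param phy A chronogram.
#' @param fractionMissing Fraction f of species to drop, `0 <= f < 1`.
#' @param seed Optional seed.
#' @export
subsampleTips <- function(phy, fractionMissing, seed = NULL) {
  stopifnot(fractionMissing >= 0, fractionMissing < 1)
  n <- length(phy$tip.label)
  keep <- round(n * (1 - fractionMissing))
  if (keep < 3) stop("subsampling would leave fewer than 3 tips")
  if (keep == n) return(phy)
  .withSeed(seed, {
    drop <- sample(phy$tip.label, n - keep)
    out <- ape::drop.tip(phy, drop)
    asChronogram(out)
  })
}

# matrix exponential of a rate matrix: eigendecomposition with a
# scaling-and-squaring fallback for defective matrices
.matExp <- function(Q, t) {
  k <- nrow(Q)
  if (k == 2L) {                           # closed form for binary chains
    a <- Q[1, 2]; b <- Q[2, 1]
    s <- a + b
    e <- if (s > 0) exp(-s * t) else 1
    p1 <- if (s > 0) b / s else 1
    P <- matrix(c(p1 + (1 - p1) * e, 1 - p1 - (1 - p1) * e,
                  p1 - p1 * e, 1 - p1 + p1 * e), 2, 2, byrow = TRUE)
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg) && abs(det(eg$vectors)) > 1e-12) {
    P <- Re(eg$vectors %*% diag(exp(eg$values * t), k) %*% solve(eg$vectors))
  } else {
    M <- Q * t
    s <- max(0L, ceiling(log2(max(abs(M)) + 1e-300)) + 1L)
    A <- M / 2^s
    P <- diag(k); term <- diag(k)
    for (i in 1:12) { term <- term %*% A / i; P <- P + term }
    for (i in seq_len(s)) P <- P %*% P
  }
  P[P < 0] <- 0
  sweep(P, 1, rowSums(P), "/")
}

#' Simulate a discrete character along a chronogram
#'
#' Runs the continuous-time Markov chain defined by rate matrix `Q` from a
#' root draw down every branch and returns the tip states.
#'
#' @param phy A chronogram (or any rooted `"phylo"`).
#' @param Q k-by-k instantaneous rate matrix (rows sum to 0, off-diagonals
#'   non-negative). States are `1..k` (or `dimnames(Q)` when given).
#' @param rootProbs Root state distribution (default uniform).
#' @param seed Optional seed.
#' @return Named integer vector of tip states.
#' @export
simulateDiscreteTrait <- function(phy, Q, rootProbs = NULL, seed = NULL) {
  k <- nrow(Q)
  stopifnot(ncol(Q) == k, all(Q[row(Q) != col(Q)] >= 0),
            max(abs(rowSums(Q))) < 1e-8)
  if (is.null(rootProbs)) rootProbs <- rep(1 / k, k)
  .withSeed(seed, {
    phy <- ape::reorder.phylo(phy, "cladewise")
    n <- length(phy$tip.label)
    state <- integer(n + phy$Nnode)
    state[n + 1L] <- sample.int(k, 1, prob = rootProbs)
    lens <- sort(unique(phy$edge.length))
    Pm <- lapply(lens, function(t) .matExp(Q, t))
    li <- match(phy$edge.length, lens)
    for (e in seq_len(nrow(phy$edge))) {
      p <- state[phy$edge[e, 1]]
      state[phy$edge[e, 2]] <- sample.int(k, 1, prob = Pm[[li[e]]][p, ])
    }
    out <- state[seq_len(n)]
    if (!is.null(dimnames(Q))) out <- rownames(Q)[out]
    stats::setNames(out, phy$tip.label)
  })
}

#' Simulate a Brownian-motion trait along a chronogram
#'
#' Normal increments with variance `sigma2 * branch length` summed from the
#' root value to each tip.
#'
#' @param phy A rooted `"phylo"`.
#' @param sigma2 Brownian rate per Myr (>= 0).
#' @param rootValue Trait value at the root.
#' @param seed Optional seed.
#' @return Named numeric vector of tip values.
#' @export
simulateContinuousTrait <- function(phy, sigma2, rootValue = 0, seed = NULL) {
  stopifnot(sigma2 >= 0)
  .withSeed(seed, {
    phy <- ape::reorder.phylo(phy, "cladewise")
    n <- length(phy$tip.label)
    val <- numeric(n + phy$Nnode)
    val[n + 1L] <- rootValue
    inc <- rnorm(nrow(phy$edge), 0, sqrt(sigma2 * phy$edge.length))
    for (e in seq_len(nrow(phy$edge)))
      val[phy$edge[e, 2]] <- val[phy$edge[e, 1]] + inc[e]
    stats::setNames(val[seq_len(n)], phy$tip.label)
  })
}

#' Parameter set for binary-state speciation and extinction models
#'
#' @param lambda0,lambda1 State-specific speciation rates per Myr.
#' @param mu0,mu1 State-specific extinction rates per Myr.
#' @param q01,q10 Transition rates per Myr between states 0 and 1.
#' @param rho0,rho1 State-specific sampling fractions in (0, 1].
#' @return A validated list of class `"bisseParams"`.
#' @export
bisseParams <- function(lambda0, lambda1, mu0 = 0, mu1 = 0, q01, q10,
                        rho0 = 1, rho1 = 1) {
  p <- list(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
            q01 = q01, q10 = q10, rho0 = rho0, rho1 = rho1)
  stopifnot(all(unlist(p) >= 0), rho0 <= 1, rho1 <= 1, rho0 > 0, rho1 > 0)
  structure(p, class = "bisseParams")
}

#' Simulate a tree jointly with a binary state (BiSSE forward process)
#'
#' Grows the tree forward with state-dependent speciation/extinction and
#' state transitions, prunes extinct lineages, and returns the reconstructed
#' chronogram with tip states.
#'
#' @param pars A [bisseParams()].
#' @param crownAge Stop at this crown age (Myr); reject if the reconstructed
#'   crown does not span it.
#' @param nTip Alternatively stop when this many extant species exist.
#' @param rootState Root state (0/1); default drawn uniformly.
#' @param seed Optional seed.
#' @param budget Resampling budget when lineages die out before the target.
#' @return List with elements `tree` (chronogram) and `states` (named 0/1
#'   vector).
#' @export
simulateBisseTree <- function(pars, crownAge = NULL, nTip = NULL,
                              rootState = NULL, seed = NULL, budget = 1e4) {
  stopifnot(inherits(pars, "bisseParams"))
  if (is.null(crownAge) && is.null(nTip))
    stop("set crownAge and/or nTip")
  .withSeed(seed, {
    for (try in seq_len(budget)) {
      res <- .simBisseOnce(pars, crownAge, nTip, rootState)
      if (!is.null(res)) return(res)
    }
    stop("BiSSE simulation budget exceeded (total extinction too likely)")
  })
}

.simBisseOnce <- function(pars, crownAge, nTip, rootState) {
  lam <- c(pars$lambda0, pars$lambda1)
  mu <- c(pars$mu0, pars$mu1)
  qq <- c(pars$q01, pars$q10)              # rate out of state 0, state 1
  rs <- if (is.null(rootState)) sample(0:1, 1) else rootState
  birth <- c(0, 0); parent <- c(NA_integer_, NA_integer_)
  death <- c(NA_real_, NA_real_); alive <- c(TRUE, TRUE)
  st <- c(rs, rs)
  t <- 0
  stopT <- if (is.null(crownAge)) Inf else crownAge
  repeat {
    ia <- which(alive)
    if (!length(ia)) return(NULL)
    s <- st[ia] + 1L
    rates <- lam[s] + mu[s] + qq[s]
    tot <- sum(rates)
    if (!is.null(nTip) && length(ia) >= nTip && is.null(crownAge)) {
      # stop at a uniform time within the current n-lineage interval
      t <- t + runif(1) * rexp(1, tot)
      break
    }
    tNext <- t + rexp(1, tot)
    if (tNext > stopT) { t <- stopT; break }
    t <- tNext
    i <- ia[sample.int(length(ia), 1, prob = rates)]
    si <- st[i] + 1L
    u <- runif(1) * (lam[si] + mu[si] + qq[si])
    if (u < lam[si]) {
      birth <- c(birth, t); parent <- c(parent, i)
      death <- c(death, NA_real_); alive <- c(alive, TRUE); st <- c(st, st[i])
    } else if (u < lam[si] + mu[si]) {
      death[i] <- t; alive[i] <- FALSE
    } else {
      st[i] <- 1L - st[i]
    }
    if (length(birth) > 1e5) stop("BiSSE simulation exceeded lineage cap")
  }
  T <- t
  lin <- data.frame(id = seq_along(birth), parent = parent, birth = birth,
                    death = ifelse(is.na(death), T, death), alive = alive)
  phy <- .reconstructFromLineages(lin, T, tipState = st)
  if (is.null(phy)) return(NULL)
  if (!is.null(nTip) && length(phy$tip.label) != nTip) return(NULL)
  states <- attr(phy, "tipStates")
  attr(phy, "tipStates") <- NULL
  list(tree = phy, states = states)
}

#' The "mussel-like" synthetic study preset
#'
#' Generates a chronogram and trait table emulating the structure of a
#' deep-sea mussel radiation: a 62-tip, 85-Myr crown-age tree grown under an
#' episodic Yule regime with a speciation burst (rates 0.01 / 0.17 / 0.05
#' events/Myr, shifts at 41.2 and 33.8 Ma), near-universal sulfur-oxidizing
#' symbionts, correlated intracellular/methanotrophic symbiont gains,
#' near-unidirectional habitat shifts from organic falls to vents/seeps,
#' a Brownian ln-shell-length trait with a habitat-linked offset, and deeper
#' depth ranges at vents/seeps. Missing-data patterns leave 48, 36 and 24
#' complete cases for the shell, methanotroph and symbiont-location
#' analyses. These are generator defaults emulating the study system, not
#' ground truth about it.
#'
#' @param seed Integer seed (required: the preset is meant to be
#'   reproducible).
#' @param nTip Tip count (default 62).
#' @param crownAge Crown age in Myr (default 85).
#' @return List with `tree`, `traits` (a trait table), and `truth` (the
#'   generating parameter values, for recovery checks).
#' @export
musselPreset <- function(seed, nTip = 62, crownAge = 85) {
  truth <- list(lambda = c(0.01, 0.17, 0.05), shiftAges = c(41.2, 33.8),
                crownAge = crownAge, nTip = nTip,
                sigma2Shell = 0.03, shellRootLn = log(30), shellVentEffect = 0.8,
                jointQ = .symbiontJointQ(), habitatQ = .habitatQ())
  .withSeed(seed, {
    tree <- .simulateTreeImpl(simConfig(crownAge = crownAge, nTip = nTip,
                                        lambda = truth$lambda,
                                        shiftAges = truth$shiftAges))
    n <- length(tree$tip.label)
    joint <- simulateDiscreteTrait(tree, truth$jointQ, rootProbs = c(1, 0, 0, 0))
    intra <- as.integer(joint %in% c("I-", "IM"))
    meth <- as.integer(joint %in% c("EM", "IM"))
    habitat <- simulateDiscreteTrait(tree, truth$habitatQ, rootProbs = c(1, 0, 0))
    sulfur <- rep(1L, n)
    lnShell <- simulateContinuousTrait(tree, truth$sigma2Shell,
                                       rootValue = truth$shellRootLn) +
      ifelse(habitat == "organic-fall", 0, truth$shellVentEffect)
    mid <- pmin(exp(rnorm(n, ifelse(habitat == "organic-fall", log(800), log(2000)),
                          0.45)), 4000)
    half <- mid * runif(n, 0.15, 0.45)
    dmax <- pmin(mid + half, 4450)
    dmin <- pmin(pmax(mid - half, 0), dmax)
    traits <- data.frame(species = tree$tip.label, habitat = habitat,
                         sulfur_symbiont = sulfur, methanotroph = meth,
                         symbiont_location = ifelse(intra == 1, "intracellular",
                                                    "extracellular"),
                         shell_length_mm = pmax(round(exp(lnShell), 1), 0.1),
                         depth_min_m = round(dmin), depth_max_m = round(dmax),
                         stringsAsFactors = FALSE)
    # nested missingness: 48 shell/habitat/depth, 36 methanotroph, 24 location
    shellSet <- sample(n, 48)
    methSet <- sample(shellSet, 36)
    locSet <- sample(methSet, 24)
    traits$habitat[-shellSet] <- NA
    traits$shell_length_mm[-shellSet] <- NA
    traits$depth_min_m[-shellSet] <- NA
    traits$depth_max_m[-shellSet] <- NA
    traits$methanotroph[-methSet] <- NA
    traits$symbiont_location[-locSet] <- NA
    traits <- validateTraitTable(traits)
    list(tree = tree, traits = traits, truth = truth)
  })
}

# joint chain over (symbiont location, methanotroph): states E-, EM, I-, IM.
# Methanotrophs are gained only in intracellular hosts; losses are rare.
.symbiontJointQ <- function() {
  states <- c("E-", "EM", "I-", "IM")
  Q <- matrix(0, 4, 4, dimnames = list(states, states))
  Q["E-", "I-"] <- 0.008   # become intracellular
  Q["I-", "E-"] <- 0.001
  Q["I-", "IM"] <- 0.012   # gain methanotrophs while intracellular
  Q["IM", "I-"] <- 0.001
  Q["IM", "EM"] <- 0.0005
  Q["EM", "E-"] <- 0.050   # methanotrophy without intracellularity decays fast
  diag(Q) <- -rowSums(Q)
  Q
}

# habitat: organic-fall -> vent/seep nearly unidirectional
.habitatQ <- function() {
  states <- c("organic-fall", "vent", "seep")
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  Q["organic-fall", "vent"] <- 0.004
  Q["organic-fall", "seep"] <- 0.004
  Q["vent", "seep"] <- 0.004
  Q["seep", "vent"] <- 0.004
  Q["vent", "organic-fall"] <- 0.0005
  Q["seep", "organic-fall"] <- 0.0005
  diag(Q) <- -rowSums(Q)
  Q
}

#' Materialise the mussel-like preset as files
#'
#' Writes `tree.nwk` and `traits.tsv` for use by tests, examples and docs.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed forwarded to [musselPreset()].
#' @return Invisibly, the list of written paths.
#' @export
writeFixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- musselPreset(seed)
  treePath <- file.path(dir, "tree.nwk")
  traitPath <- file.path(dir, "traits.tsv")
  writeNewick(pre$tree, treePath)
  writeTraitTable(pre$traits, traitPath)
  invisible(list(tree = treePath, traits = traitPath))
}
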