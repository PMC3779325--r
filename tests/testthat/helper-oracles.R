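# Shared fixtures and independent oracle implementations used across the
# suite. Oracles deliberately avoid the package's own computational paths:
# numerical quadrature for intensity integrals, high-resolution ODE
# integration (deSolve) for survival/data equations, exhaustive enumeration
# for small-tree pruning likelihoods.

toyTree3 <- function() parseNewick("((A:1,B:1):1,C:2);")

# one mussel-like preset per test run (generation is seeded and cheap)
presetCache <- new.env()
getPreset <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(presetCache[[key]])) presetCache[[key]] <- musselPreset(seed)
  presetCache[[key]]
}

randomYuleTree <- function(n, T = 20, lambda = 0.1, seed = NULL) {
  simulateTree(simConfig(crownAge = T, nTip = n, lambda = lambda), seed = seed)
}

# ---- quadrature oracle for the pure-birth-family likelihood ----------------
# lnL = sum over events log(N * lambda(age)) - integral N(t) lambda(t) dt,
# with the integral done by adaptive quadrature over each inter-event
# interval instead of the closed forms used by the implementation
oracleDivLoglik <- function(bt, rateAt) {
  n <- length(bt) + 1L
  bounds <- c(bt[1], bt[-1], 0)
  counts <- seq.int(2L, n)
  lnL <- 0
  for (i in seq_along(counts)) {
    hi <- bounds[i]; lo <- bounds[i + 1]
    N <- counts[i]
    f <- function(a) vapply(a, function(ai) rateAt(ai, N), numeric(1))
    if (hi > lo)
      lnL <- lnL - N * stats::integrate(f, lo, hi, rel.tol = 1e-12,
                                        subdivisions = 500L)$value
    if (i < length(counts))
      lnL <- lnL + log(N * rateAt(bounds[i + 1] + 1e-12, N))
  }
  lnL
}

# ---- deSolve oracle for the mass-extinction birth-death likelihood ---------
# integrates dE/ds, dlogD/ds with lsoda piecewise between events and
# assembles the crown-conditioned likelihood from branching times
oracleMeLoglik <- function(bt, lambda, mu, events) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  n <- length(bt) + 1L
  evAge <- events$age; evRho <- events$rho
  o <- order(evAge); evAge <- evAge[o]; evRho <- evRho[o]
  profile <- function(age) {
    state <- c(E = 0, logD = 0)
    s0 <- 0
    for (j in seq_along(evAge)) {
      if (evAge[j] >= age) break
      state <- .advance(state, s0, evAge[j], lambda, mu)
      state["E"] <- (1 - evRho[j]) + evRho[j] * state["E"]
      state["logD"] <- state["logD"] + log(evRho[j])
      s0 <- evAge[j]
    }
    .advance(state, s0, age, lambda, mu)
  }
  prof <- vapply(bt, profile, numeric(2))
  unname(lfactorial(n - 1) + (n - 2) * log(lambda) + sum(prof["logD", ]) +
           prof["logD", 1] - 2 * log(1 - prof["E", 1]))
}

# (E, logD) at one age via the ODE route
oracleMeProfile <- function(age, lambda, mu, events) {
  evAge <- events$age; evRho <- events$rho
  o <- order(evAge); evAge <- evAge[o]; evRho <- evRho[o]
  state <- c(E = 0, logD = 0)
  s0 <- 0
  for (j in seq_along(evAge)) {
    if (evAge[j] >= age) break
    state <- .advance(state, s0, evAge[j], lambda, mu)
    state["E"] <- (1 - evRho[j]) + evRho[j] * state["E"]
    state["logD"] <- state["logD"] + log(evRho[j])
    s0 <- evAge[j]
  }
  .advance(state, s0, age, lambda, mu)
}

.advance <- function(state, from, to, lambda, mu) {
  if (to <= from + 1e-14) return(state)
  f <- function(s, y, parms) {
    list(c(mu - (lambda + mu) * y[1] + lambda * y[1]^2,
           2 * lambda * y[1] - (lambda + mu)))
  }
  out <- deSolve::lsoda(state, c(from, to), f, NULL,
                        rtol = 1e-11, atol = 1e-12)
  stats::setNames(out[2, 2:3], c("E", "logD"))
}

# ---- deSolve oracle for the BiSSE likelihood -------------------------------
oracleBisseLoglik <- function(phy, states, pars, rootWeighting = "fitzjohn") {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  phy <- ape::reorder.phylo(phy, "postorder")
  n <- length(phy$tip.label)
  states <- states[phy$tip.label]
  deriv <- function(t, y, p) {
    with(as.list(p), {
      E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
      list(c(mu0 - (lambda0 + mu0 + q01) * E0 + q01 * E1 + lambda0 * E0^2,
             mu1 - (lambda1 + mu1 + q10) * E1 + q10 * E0 + lambda1 * E1^2,
             -(lambda0 + mu0 + q01) * D0 + q01 * D1 + 2 * lambda0 * E0 * D0,
             -(lambda1 + mu1 + q10) * D1 + q10 * D0 + 2 * lambda1 * E1 * D1))
    })
  }
  vals <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) {
    s <- states[i]
    vals[[i]] <- c(1 - pars$rho0, 1 - pars$rho1,
                   if (is.na(s)) c(pars$rho0, pars$rho1)
                   else if (s == 0) c(pars$rho0, 0) else c(0, pars$rho1))
  }
  logscale <- 0
  accum <- vector("list", n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    y0 <- vals[[ch]]
    out <- deSolve::lsoda(y0, c(0, phy$edge.length[e]), deriv,
                          unclass(pars)[1:6], rtol = 1e-11, atol = 1e-13)
    y <- out[2, -1]
    accum[[p]] <- c(accum[[p]], list(y))
    if (length(accum[[p]]) == 2) {
      a <- accum[[p]][[1]]; b <- accum[[p]][[2]]
      root <- p
      if (p == n + 1L) {
        D <- c(a[3] * b[3], a[4] * b[4])          # no speciation factor at root
      } else {
        D <- c(pars$lambda0 * a[3] * b[3], pars$lambda1 * a[4] * b[4])
      }
      m <- sum(abs(D)); D <- D / m; logscale <- logscale + log(m)
      vals[[p]] <- c((a[1] + b[1]) / 2, (a[2] + b[2]) / 2, D)
    }
  }
  D <- vals[[n + 1L]][3:4]
  w <- if (rootWeighting == "fitzjohn") D / sum(D) else c(0.5, 0.5)
  log(sum(w * D)) + logscale
}

# ---- exhaustive enumeration oracle for Mk on small trees -------------------
# sums the joint probability over every internal-state assignment
oracleMkLoglik <- function(phy, tipPartials, Q, rootPrior) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label)
  k <- nrow(Q)
  nInt <- phy$Nnode
  Pm <- lapply(seq_len(nrow(phy$edge)),
               function(e) as.matrix(Matrix::expm(Q * phy$edge.length[e])))
  states <- as.matrix(expand.grid(rep(list(seq_len(k)), nInt)))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    assign <- states[r, ]
    names(assign) <- as.character((n + 1L):(n + nInt))
    pr <- rootPrior[assign[1]]
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      sp <- assign[as.character(p)]
      if (ch <= n) {
        pr <- pr * sum(Pm[[e]][sp, ] * tipPartials[ch, ])
      } else {
        pr <- pr * Pm[[e]][sp, assign[as.character(ch)]]
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

# marginal node probabilities by the same enumeration
oracleMkMarginals <- function(phy, tipPartials, Q, rootPrior) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label)
  k <- nrow(Q)
  nInt <- phy$Nnode
  Pm <- lapply(seq_len(nrow(phy$edge)),
               function(e) as.matrix(Matrix::expm(Q * phy$edge.length[e])))
  states <- as.matrix(expand.grid(rep(list(seq_len(k)), nInt)))
  marg <- matrix(0, nInt, k)
  for (r in seq_len(nrow(states))) {
    assign <- states[r, ]
    names(assign) <- as.character((n + 1L):(n + nInt))
    pr <- rootPrior[assign[1]]
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      sp <- assign[as.character(p)]
      if (ch <= n) pr <- pr * sum(Pm[[e]][sp, ] * tipPartials[ch, ])
      else pr <- pr * Pm[[e]][sp, assign[as.character(ch)]]
    }
    for (j in seq_len(nInt)) marg[j, assign[j]] <- marg[j, assign[j]] + pr
  }
  marg / rowSums(marg)
}

# ---- brute-force Pagel likelihood over the 4-state joint chain -------------
oraclePagelLoglik <- function(phy, jointStates, Q4) {
  n <- length(phy$tip.label)
  tipL <- matrix(0, n, 4)
  tipL[cbind(seq_len(n), jointStates[phy$tip.label])] <- 1
  oracleMkLoglik(phy, tipL, Q4, rep(0.25, 4))
}
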