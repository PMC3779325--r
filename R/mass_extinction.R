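#' Parameters of a birth-death process with mass-extinction events
#'
#' @param lambda Speciation rate per Myr (> 0).
#' @param mu Extinction rate per Myr (>= 0).
#' @param events Data frame with columns `age` (Myr before present) and
#'   `rho` (survival fraction in (0, 1]); each lineage alive at the event
#'   survives independently with probability `rho`.
#' @return Validated list of class `"meParams"`.
#' @export
meParams <- function(lambda, mu = 0, events = NULL) {
  stopifnot(lambda > 0, mu >= 0)
  if (is.null(events))
    events <- data.frame(age = numeric(0), rho = numeric(0))
  stopifnot(all(events$rho > 0), all(events$rho <= 1), all(events$age > 0))
  events <- events[order(events$age), , drop = FALSE]
  structure(list(lambda = lambda, mu = mu, events = events),
            class = "meParams")
}

# Piecewise-analytic survival machinery for constant-rate birth-death with
# instantaneous mass extinctions. E(s) = P(no sampled descendant | alive at
# age s); logD(s) = log per-lineage density propagator from the present to
# age s. Between events both have closed forms; crossing an event applies
# E <- (1 - rho) + rho E and D <- rho D.
.meBreakpoints <- function(lambda, mu, events) {
  r <- lambda - mu
  if (abs(r) < 1e-10) r <- 1e-10           # critical process guard
  evAge <- events$age; evRho <- events$rho
  brk <- c(0, evAge)                       # ascending piece starts
  Ebrk <- numeric(length(brk)); logDbrk <- numeric(length(brk))
  for (j in seq_along(evAge)) {
    E0 <- Ebrk[j]
    A <- lambda * (1 - E0); B <- mu - lambda * E0
    d <- evAge[j] - brk[j]
    eg <- exp(-r * d)
    Ebrk[j + 1] <- (1 - evRho[j]) +
      evRho[j] * (mu * (1 - E0) - B * eg) / (A - B * eg)
    logDbrk[j + 1] <- logDbrk[j] + log(evRho[j]) +
      r * d - 2 * (log(A * exp(r * d) - B) - log(A - B))
  }
  list(r = r, brk = brk, E = Ebrk, logD = logDbrk)
}

.meProfiles <- function(ages, lambda, mu, events) {
  bp <- .meBreakpoints(lambda, mu, events)
  r <- bp$r
  idx <- findInterval(ages, bp$brk)
  E0 <- bp$E[idx]
  A <- lambda * (1 - E0); B <- mu - lambda * E0
  d <- ages - bp$brk[idx]
  eg <- exp(-r * d)
  list(E = (mu * (1 - E0) - B * eg) / (A - B * eg),
       logD = bp$logD[idx] + r * d - 2 * (log(A * exp(r * d) - B) - log(A - B)))
}

# exact conditional node-age sampler for constant-rate birth-death with
# mass extinctions: conditioned on crown age T and n tips the n - 2
# non-crown node ages are iid with density proportional to
# lambda * Dtilde(x); piecewise closed-form CDF, inverted analytically
.sampleMEAges <- function(n, T, lambda, mu, events = NULL) {
  if (n == 2) return(numeric(0))
  if (is.null(events)) events <- data.frame(age = numeric(0), rho = numeric(0))
  events <- events[events$age < T, , drop = FALSE]
  bp <- .meBreakpoints(lambda, mu, events)
  r <- bp$r
  ends <- c(bp$brk[-1], T)
  npieces <- length(bp$brk)
  A <- lambda * (1 - bp$E); B <- mu - lambda * bp$E
  Da <- exp(bp$logD)
  # mass of each piece: int lambda * Dtilde over the piece
  mass <- numeric(npieces)
  for (j in seq_len(npieces)) {
    d <- ends[j] - bp$brk[j]
    mass[j] <- lambda * Da[j] * (A[j] - B[j])^2 / (r * A[j]) *
      (1 / (A[j] - B[j]) - 1 / (A[j] * exp(r * d) - B[j]))
  }
  cum <- c(0, cumsum(mass))
  u <- runif(n - 2) * cum[npieces + 1]
  j <- findInterval(u, cum, rightmost.closed = TRUE)
  j <- pmin(j, npieces)
  m <- u - cum[j]                          # residual mass within the piece
  v <- 1 / (A[j] - B[j]) - m * r * A[j] / (lambda * Da[j] * (A[j] - B[j])^2)
  dd <- log((B[j] + 1 / v) / A[j]) / r
  pmin(pmax(bp$brk[j] + dd, 0), T)
}

#' Birth-death log-likelihood with mass-extinction events
#'
#' Reconstructed-process log-likelihood of a chronogram under a
#' constant-rate birth-death process punctuated by instantaneous
#' mass-extinction events, conditioned on the crown age and survival of both
#' crown lineages. With all survival fractions at 1 this reduces exactly to
#' the plain birth-death likelihood of [divLoglik()].
#'
#' @param tree A chronogram, or a branching-times vector from
#'   [branchingTimes()].
#' @param params A [meParams()].
#' @return Log-likelihood.
#' @export
meLoglik <- function(tree, params) {
  stopifnot(inherits(params, "meParams"))
  bt <- if (inherits(tree, "phylo")) branchingTimes(tree) else tree
  n <- .validBt(bt)
  crown <- bt[1]
  if (nrow(params$events) && any(params$events$age >= crown))
    stop("mass-extinction event age outside the tree span (crown = ",
         signif(crown, 6), ")")
  ev <- params$events
  me_loglik_cpp(bt, params$lambda, params$mu, ev$age, ev$rho)
}

# ML fit of (lambda, mu) with the event schedule held fixed (rho free
# optionally); returns fitted params and lnL
.fitMe <- function(bt, events = NULL, freeRho = FALSE, restarts = 2) {
  bt <- as.numeric(bt)
  lamHat <- length(bt[-1]) /
    (bt[1] + sum(bt))                      # closed-form Yule start
  hasEvents <- !is.null(events) && nrow(events) > 0
  evAge <- if (hasEvents) sort(events$age) else numeric(0)
  evRho0 <- if (hasEvents) events$rho[order(events$age)] else numeric(0)
  nll <- function(p) {
    lam <- exp(p[1])
    mu <- lam * stats::plogis(p[2]) * 0.999
    evRho <- if (hasEvents && freeRho) rep(stats::plogis(p[3]), length(evAge))
             else evRho0
    v <- -me_loglik_cpp(bt, lam, mu, evAge, evRho)
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(log(lamHat), -3, if (hasEvents && freeRho) 0)
  o <- .optimMultistart(nll, start, restarts)
  lam <- exp(o$par[1]); mu <- lam * stats::plogis(o$par[2]) * 0.999
  ev <- events
  if (hasEvents && freeRho) ev$rho <- stats::plogis(o$par[3])
  # mu = 0 boundary
  nll0 <- nll(c(o$par[1], -30, if (hasEvents && freeRho) o$par[3]))
  fit <- meParams(lam, mu, ev)
  lnL <- -o$value
  if (nll0 < o$value) {
    fit <- meParams(lam, 0, ev); lnL <- -nll0
  }
  list(params = fit, lnL = lnL, convergence = o$convergence)
}

#' Simulation test for a mass-extinction event
#'
#' Fits a plain birth-death model (H0) and a birth-death model with a
#' mass-extinction event of survival `rho` at age `tME` (H1, `rho` fixed by
#' default so both models have two free parameters) to the input chronogram.
#' The observed statistic `dlnL = lnL(H1) - lnL(H0)` is calibrated against
#' trees simulated under the fitted H0, conditioned on the observed crown
#' age and tip count; trees simulated under the fitted H1 provide the
#' alternative distribution and lineage-through-time envelopes.
#'
#' @param tree A chronogram.
#' @param tME Event age (Myr).
#' @param rho Hypothesised survival fraction (default 0.05).
#' @param replicates Simulation count per hypothesis (>= 100).
#' @param freeRho Estimate `rho` instead of fixing it.
#' @param alternativeSims Also simulate under H1 (needed for the H1
#'   histogram and envelopes; switch off for pure size calibration).
#' @param fitRestarts Optimiser restarts per model fit (observed and
#'   simulated); the two-parameter surfaces are smooth, so 1-2 suffice.
#' @param seed Optional seed.
#' @return A `"meTest"` object: observed `dlnL`, null and alternative
#'   samples, H0's 5% rejection level, pseudocount p-value, and LTT
#'   envelopes.
#' @export
meExtinctionTest <- function(tree, tME = 57, rho = 0.05, replicates = 1000,
                             freeRho = FALSE, alternativeSims = TRUE,
                             fitRestarts = 2, seed = NULL) {
  stopifnot(replicates >= 100)
  bt <- branchingTimes(tree)
  n <- attr(bt, "n")
  crown <- bt[1]
  if (tME <= 0 || tME >= crown)
    stop("event age must lie inside (0, crown age)")
  ev <- data.frame(age = tME, rho = rho)
  h0 <- .fitMe(bt, events = NULL, restarts = fitRestarts)
  h1 <- .fitMe(bt, events = ev, freeRho = freeRho, restarts = fitRestarts)
  obs <- h1$lnL - h0$lnL
  statOn <- function(b) {
    f0 <- .fitMe(b, events = NULL, restarts = fitRestarts)
    f1 <- .fitMe(b, events = ev, freeRho = freeRho, restarts = fitRestarts)
    f1$lnL - f0$lnL
  }
  .withSeed(seed, {
    drawBt <- function(params) {
      ages <- c(crown, sort(.sampleMEAges(n, crown, params$lambda, params$mu,
                                          params$events), decreasing = TRUE))
      structure(ages, n = n)
    }
    nullBtList <- replicate(replicates, drawBt(h0$params), simplify = FALSE)
    nullStats <- vapply(nullBtList, statOn, numeric(1))
    p <- (1 + sum(nullStats >= obs)) / (1 + replicates)
    altStats <- NULL
    envH1 <- NULL
    grid <- seq(crown, 0, length.out = 101)
    lttOn <- function(b) {
      # lineage count at each grid age
      1 + findInterval(-grid, -sort(b, decreasing = TRUE) - 1e-12)
    }
    envH0 <- apply(vapply(nullBtList, lttOn, numeric(length(grid))), 1,
                   quantile, probs = c(0.025, 0.975))
    if (alternativeSims) {
      altBt <- replicate(replicates, drawBt(h1$params), simplify = FALSE)
      altStats <- vapply(altBt, statOn, numeric(1))
      envH1 <- apply(vapply(altBt, lttOn, numeric(length(grid))), 1,
                     quantile, probs = c(0.025, 0.975))
    }
    structure(list(observed = obs, null = nullStats, alternative = altStats,
                   p.value = p,
                   rejectionLevel = unname(quantile(nullStats, 0.95)),
                   h0 = h0, h1 = h1, tME = tME, rho = rho,
                   replicates = replicates,
                   ltt = list(age = grid, h0 = envH0, h1 = envH1)),
              class = "meTest")
  })
}

#' @export
print.meTest <- function(x, ...) {
  cat(sprintf(
    paste0("Mass-extinction test (event at %.1f Ma, rho = %.2f):\n",
           "  observed dlnL = %.3f, H0 5%% rejection level = %.3f, p = %.4g\n",
           "  H0: lambda = %.4f, mu = %.4f; H1: lambda = %.4f, mu = %.4f\n"),
    x$tME, x$rho, x$observed, x$rejectionLevel, x$p.value,
    x$h0$params$lambda, x$h0$params$mu,
    x$h1$params$lambda, x$h1$params$mu))
  invisible(x)
}
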