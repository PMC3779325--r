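#' BiSSE log-likelihood
#'
#' Binary-state speciation and extinction likelihood: the coupled extinction
#' (E) and data (D) ordinary differential equations are integrated rootward
#' along every branch with an adaptive Runge-Kutta scheme, D values are
#' multiplied by the state's speciation rate at each internal node merge
#' (except the root), and the root states are combined by FitzJohn weighting
#' (each state weighted by its share of the root likelihood) or equally.
#' State-specific sampling fractions enter the tip initial conditions
#' (`D = rho` for the observed state, `E = 1 - rho`). Missing tip states are
#' ambiguous: `D = rho` in both states.
#'
#' @param phy A strictly bifurcating chronogram.
#' @param states Named 0/1 vector keyed by tip label; NA = missing.
#' @param pars A [bisseParams()].
#' @param rootWeighting `"fitzjohn"` (default) or `"equal"`.
#' @param conditionSurvival Divide by the probability that both crown
#'   lineages survive and speciate (off by default).
#' @param rtol Relative tolerance of the branch integrator.
#' @return Log-likelihood.
#' @export
bisseLoglik <- function(phy, states, pars, rootWeighting = c("fitzjohn", "equal"),
                        conditionSurvival = FALSE, rtol = 1e-8) {
  rootWeighting <- match.arg(rootWeighting)
  stopifnot(inherits(pars, "bisseParams"))
  if (!ape::is.binary.phylo(phy))
    stop("tree must be strictly bifurcating; resolve polytomies with prepareTree()")
  n <- length(phy$tip.label)
  states <- states[phy$tip.label]
  if (!all(is.na(states) | states %in% c(0, 1)))
    stop("states must be 0/1/NA")
  tipD <- matrix(0, n, 2)
  tipD[, 1] <- ifelse(is.na(states) | states == 0, pars$rho0, 0)
  tipD[, 2] <- ifelse(is.na(states) | states == 1, pars$rho1, 0)
  po <- .postorderEdges(phy)
  bisse_loglik_cpp(po$edge, po$len, n, tipD,
                   c(1 - pars$rho0, 1 - pars$rho1),
                   with(pars, c(lambda0, lambda1, mu0, mu1, q01, q10)),
                   if (rootWeighting == "fitzjohn") 0L else 1L,
                   conditionSurvival, rtol)
}

#' Character-dependent vs. simple Yule speciation models
#'
#' Fits the Yule-constrained model pair used to ask whether a binary
#' character (e.g. hosting methanotrophic or intracellular symbionts)
#' changes speciation rates: H0 is a single-rate Yule model with the
#' character evolving neutrally (`lambda0 = lambda1 = lambda_Yule`, `mu = 0`),
#' H1 frees `lambda0` and `lambda1`. Both share free transition rates and
#' the given state-specific sampling fractions, and are compared by a
#' likelihood-ratio test with 1 degree of freedom. A full BiSSE mode with
#' free extinction rates is available.
#'
#' @inheritParams bisseLoglik
#' @param samplingFractions Length-2 vector: fractions of extant species in
#'   state 0 and state 1 present in the tree (the assumed sampling-bias
#'   ratio).
#' @param fullBisse Also free `mu0`, `mu1` (adds 2 d.f. to H1 and 1 to H0).
#' @param restarts Optimiser restarts.
#' @return An `"sseTest"`: `lnL0`, `lnL1`, `lambdaYule`, `lambda0`,
#'   `lambda1`, `LR = 2 (lnL1 - lnL0)`, `df`, `p.value`, fitted transition
#'   rates.
#' @export
fitSseModels <- function(phy, states, samplingFractions = c(1, 1),
                         fullBisse = FALSE, rootWeighting = "fitzjohn",
                         restarts = 3, rtol = 1e-7) {
  states <- states[phy$tip.label]
  if (sum(!is.na(states)) < 10)
    stop("need at least 10 tips with observed states")
  n <- length(phy$tip.label)
  tipD <- matrix(0, n, 2)
  tipD[, 1] <- ifelse(is.na(states) | states == 0, samplingFractions[1], 0)
  tipD[, 2] <- ifelse(is.na(states) | states == 1, samplingFractions[2], 0)
  tipE <- 1 - samplingFractions
  po <- .postorderEdges(phy)
  rootType <- if (rootWeighting == "fitzjohn") 0L else 1L
  lnLfor <- function(lam0, lam1, mu0, mu1, q01, q10) {
    v <- bisse_loglik_cpp(po$edge, po$len, n, tipD, tipE,
                          c(lam0, lam1, mu0, mu1, q01, q10),
                          rootType, FALSE, rtol)
    if (!is.finite(v)) -1e10 else v
  }
  bt <- branchingTimes(phy)
  lamHat <- max(.fitPureBirth(bt)$pars$r1, 1e-4)
  qHat <- max(0.5 / bt[1], 1e-4)
  # H0: single speciation rate
  nll0 <- function(p) {
    mu <- if (fullBisse) exp(p[4]) else 0
    -lnLfor(exp(p[1]), exp(p[1]), mu, mu, exp(p[2]), exp(p[3]))
  }
  o0 <- .optimMultistart(nll0, c(log(lamHat), log(qHat), log(qHat),
                                 if (fullBisse) log(lamHat / 4)),
                         restarts, lower = -15, upper = 3)
  # H1: state-specific speciation rates, warm-started from H0
  nll1 <- function(p) {
    mus <- if (fullBisse) exp(p[5:6]) else c(0, 0)
    -lnLfor(exp(p[1]), exp(p[2]), mus[1], mus[2], exp(p[3]), exp(p[4]))
  }
  s1 <- c(o0$par[1], o0$par[1], o0$par[2], o0$par[3],
          if (fullBisse) rep(o0$par[4], 2))
  o1 <- .optimMultistart(nll1, s1, restarts, lower = -15, upper = 3)
  if (o1$value > o0$value) o1$value <- o0$value  # nested: LR clamped at 0
  LR <- 2 * (o0$value - o1$value)
  df <- if (fullBisse) 2L else 1L
  structure(list(
    lnL0 = -o0$value, lnL1 = -o1$value,
    lambdaYule = exp(o0$par[1]),
    lambda0 = exp(o1$par[1]), lambda1 = exp(o1$par[2]),
    q01 = exp(o1$par[3]), q10 = exp(o1$par[4]),
    mu0 = if (fullBisse) exp(o1$par[5]) else 0,
    mu1 = if (fullBisse) exp(o1$par[6]) else 0,
    samplingFractions = samplingFractions,
    LR = LR, df = df, p.value = stats::pchisq(LR, df, lower.tail = FALSE),
    nObserved = sum(!is.na(states))),
    class = "sseTest")
}

#' @export
print.sseTest <- function(x, ...) {
  cat(sprintf(
    paste0("State-dependent speciation test (Yule-constrained BiSSE):\n",
           "  lambda0 = %.4f, lambda1 = %.4f, lambda_Yule = %.4f\n",
           "  LR = %.3f (%d d.f.), p = %.4g  [sampling %0.2f : %0.2f, %d tips]\n"),
    x$lambda0, x$lambda1, x$lambdaYule, x$LR, x$df, x$p.value,
    x$samplingFractions[1], x$samplingFractions[2], x$nObserved))
  invisible(x)
}
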