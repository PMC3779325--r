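#' Log-likelihood of a diversification model on branching times
#'
#' Reconstructed-process log-likelihoods conditioned on the crown age, for
#' the classic model family fitted to branching times: constant-rate pure
#' birth; constant-rate birth-death parameterised by net diversification
#' `r1 = lambda - mu` and extinction fraction `a = mu / lambda`;
#' density-dependent logistic (`lambda_N = r1 (1 - N/k)`) and exponential
#' (`lambda_N = r1 * N^(-xp)`, so a negative `xp` means the rate grows with
#' standing diversity) variants; two- and three-rate Yule models with shift
#' ages `s1 (> s2)`; and a Weibull-shaped time-varying pure-birth decline
#' with shape `beta` and scale `b` measured forward from the start of the
#' analysis window.
#'
#' For all pure-birth-type models the likelihood is
#' `sum(log intensity at each event) - integral of total birth intensity`,
#' including the combinatorial lineage factors, so that nested models agree
#' exactly in their shared limits. The birth-death model uses the standard
#' closed form for the reconstructed process conditioned on crown age and
#' survival of both crown lineages.
#'
#' @param bt Branching times from [branchingTimes()] (descending, crown
#'   first).
#' @param model One of `"pure_birth"`, `"birth_death"`, `"DDL"`, `"DDX"`,
#'   `"yule_2rate"`, `"yule_3rate"`, `"weibull_decline"`.
#' @param pars Named numeric vector/list of parameters (see Details above:
#'   `r1`, `r2`, `r3`, `a`, `k`, `xp`, `s1`, `s2`, `b`, `beta`).
#' @param window Optional analysis window: the age at which the window
#'   opens (likelihood of events younger than this, given the lineage count
#'   then). Default covers the whole tree. Only pure-birth-type models
#'   support windows.
#' @return Log-likelihood (natural log).
#' @export
#' @examples
#' bt <- structure(c(10, 6, 3), n = 4L)
#' divLoglik(bt, "pure_birth", c(r1 = 2 / 29))
divLoglik <- function(bt, model, pars, window = NULL) {
  n <- .validBt(bt)
  pars <- as.list(pars)
  model <- match.arg(model, c("pure_birth", "birth_death", "DDL", "DDX",
                              "yule_2rate", "yule_3rate", "weibull_decline"))
  if (model == "birth_death") {
    if (!is.null(window)) stop("birth_death does not support an analysis window")
    .bdLoglik(bt, pars$r1, pars$a)
  } else {
    rateFn <- .rateFunction(model, pars, n)
    .pbLoglik(bt, rateFn, window)
  }
}

# builds lambda(age, N) for the pure-birth family together with the exact
# integral of lambda over an age interval at fixed N (all supported rate
# functions have closed-form cumulative intensities)
.rateFunction <- function(model, pars, n) {
  seg <- function(lo, hi, a, b) pmax(0, pmin(hi, a) - pmax(lo, b))
  switch(model,
    pure_birth = {
      stopifnot(pars$r1 >= 0)
      list(rate = function(age, N) rep_len(pars$r1, length(age)),
           integral = function(lo, hi, N) pars$r1 * (hi - lo))
    },
    DDL = {
      stopifnot(pars$r1 >= 0, pars$k > n)
      list(rate = function(age, N) pars$r1 * (1 - N / pars$k),
           integral = function(lo, hi, N) pars$r1 * (1 - N / pars$k) * (hi - lo))
    },
    DDX = {
      stopifnot(pars$r1 >= 0)
      list(rate = function(age, N) pars$r1 * N^(-pars$xp),
           integral = function(lo, hi, N) pars$r1 * N^(-pars$xp) * (hi - lo))
    },
    yule_2rate = {
      stopifnot(pars$r1 >= 0, pars$r2 >= 0)
      list(rate = function(age, N) ifelse(age > pars$s1, pars$r1, pars$r2),
           integral = function(lo, hi, N)
             pars$r1 * seg(lo, hi, Inf, pars$s1) + pars$r2 * seg(lo, hi, pars$s1, 0))
    },
    yule_3rate = {
      stopifnot(pars$r1 >= 0, pars$r2 >= 0, pars$r3 >= 0, pars$s1 > pars$s2)
      list(rate = function(age, N) ifelse(age > pars$s1, pars$r1,
                                          ifelse(age > pars$s2, pars$r2, pars$r3)),
           integral = function(lo, hi, N)
             pars$r1 * seg(lo, hi, Inf, pars$s1) +
             pars$r2 * seg(lo, hi, pars$s1, pars$s2) +
             pars$r3 * seg(lo, hi, pars$s2, 0))
    },
    weibull_decline = {
      stopifnot(pars$b > 0, pars$beta > 0)
      # Weibull-hazard-shaped rate in age: for beta > 1 the speciation rate
      # is higher at older ages and declines smoothly toward the present;
      # beta = 1 recovers a constant rate 1/b
      list(rate = function(age, N) {
             u <- pmax(age, 1e-300)
             (pars$beta / pars$b) * (u / pars$b)^(pars$beta - 1)
           },
           integral = function(lo, hi, N)   # cumulative hazard (age/b)^beta
             (hi / pars$b)^pars$beta - (lo / pars$b)^pars$beta)
    },
    stop("unknown model"))
}

# generic piecewise evaluation: sum of event log-intensities minus the
# integral of N(t) * lambda(t, N) between events
.pbLoglik <- function(bt, rateFn, window = NULL) {
  n <- .validBt(bt)
  crown <- bt[1]
  wstart <- if (is.null(window)) crown else window
  stopifnot(wstart > 0, wstart <= crown + 1e-9)
  inWin <- bt < wstart - 1e-12
  events <- bt[inWin]                       # ages of events inside the window
  N0 <- 2L + sum(!inWin) - 1L               # lineages when the window opens
  if (is.null(window)) N0 <- 2L
  # interval boundaries (descending): window start, events, 0
  bounds <- c(wstart, events, 0)
  counts <- N0 + seq(0L, length(events))    # lineage count in each interval
  lnL <- 0
  for (i in seq_along(counts)) {
    hi <- bounds[i]; lo <- bounds[i + 1]
    N <- counts[i]
    lnL <- lnL - N * rateFn$integral(lo, hi, N)
    if (i <= length(events)) {
      lamEv <- rateFn$rate(events[i] + 1e-12, N)   # rate just before the event
      if (lamEv <= 0) return(-Inf)
      lnL <- lnL + log(N * lamEv)
    }
  }
  lnL
}

# Nee et al. reconstructed-process likelihood, conditioned on crown age and
# survival of both crown lineages; parameters r = lambda - mu, a = mu/lambda
.bdLoglik <- function(bt, r, a) {
  n <- .validBt(bt)
  if (r <= 0 || a < 0 || a >= 1) return(-Inf)
  x <- bt                                    # descending, x[1] = crown age
  lfactorial(n - 1) + (n - 2) * log(r) + r * sum(x[-1]) +
    n * log(1 - a) - 2 * sum(log(exp(r * x) - a))
}

#' Akaike information criteria
#'
#' @param lnL Log-likelihood.
#' @param kparams Number of free parameters.
#' @param nObs Number of observations (needed for AICc; here the number of
#'   branching times).
#' @return Named vector with `AIC` and, when `nObs` is supplied, `AICc`.
#' @export
#' @examples
#' aicScores(-54.49, 1)  # AIC 111.0 at 1 d.p.
aicScores <- function(lnL, kparams, nObs = NULL) {
  stopifnot(kparams >= 0)
  aic <- -2 * lnL + 2 * kparams
  if (is.null(nObs)) return(c(AIC = aic))
  if (nObs <= kparams + 1)
    stop("AICc undefined: nObs must exceed kparams + 1")
  c(AIC = aic, AICc = aic + 2 * kparams * (kparams + 1) / (nObs - kparams - 1))
}

.modelPars <- list(
  pure_birth = "r1", birth_death = c("r1", "a"), DDL = c("r1", "k"),
  DDX = c("r1", "xp"), yule_2rate = c("r1", "r2", "s1"),
  yule_3rate = c("r1", "r2", "r3", "s1", "s2"),
  weibull_decline = c("b", "beta"))

.modelType <- c(pure_birth = "RC", birth_death = "RC", DDL = "RV", DDX = "RV",
                yule_2rate = "RV", yule_3rate = "RV", weibull_decline = "RV")

#' Fit a diversification model by maximum likelihood
#'
#' Pure-birth and the piecewise Yule models have closed-form conditional
#' MLEs (per-segment rate = events / lineage-time; shift ages enumerated
#' over the observed branching times, where the profile likelihood attains
#' its maxima). The remaining models use bounded quasi-Newton optimisation
#' with multiple jittered restarts on log-scale parameters.
#'
#' @inheritParams divLoglik
#' @param nObs Observations used for AICc (default `length(bt)`).
#' @param restarts Optimiser restarts for the non-closed-form models.
#' @return A `"divModelFit"`: list with `model`, `pars`, `lnL`, `k`, `AIC`,
#'   `AICc`, `convergence`.
#' @export
fitDivModel <- function(bt, model, window = NULL, nObs = length(bt),
                        restarts = 5) {
  n <- .validBt(bt)
  model <- match.arg(model, names(.modelPars))
  fit <- switch(model,
    pure_birth = .fitPureBirth(bt, window),
    birth_death = .fitBD(bt, restarts),
    DDL = .fitDDL(bt, restarts),
    DDX = .fitDDX(bt, restarts),
    yule_2rate = .fitYuleShift(bt, 1L),
    yule_3rate = .fitYuleShift(bt, 2L),
    weibull_decline = .fitWeibull(bt, window, restarts))
  k <- length(.modelPars[[model]])
  ic <- aicScores(fit$lnL, k, nObs)
  structure(list(model = model, pars = fit$pars, lnL = fit$lnL, k = k,
                 AIC = unname(ic["AIC"]), AICc = unname(ic["AICc"]),
                 convergence = fit$convergence %||% 0L, nObs = nObs),
            class = "divModelFit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.divModelFit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AIC = %.2f\n",
              x$model, x$lnL, x$k, x$AIC))
  print(unlist(x$pars))
  invisible(x)
}

# event count and total lineage-time inside [0, wstart]
.btSuffStats <- function(bt, wstart = NULL) {
  n <- .validBt(bt)
  crown <- bt[1]
  if (is.null(wstart)) wstart <- crown
  inWin <- bt < wstart - 1e-12
  events <- bt[inWin]
  N0 <- if (wstart >= crown - 1e-12) 2L else 2L + sum(!inWin) - 1L
  bounds <- c(wstart, events, 0)
  counts <- N0 + seq(0L, length(events))
  list(kEvents = length(events),
       lineageTime = sum(counts * (bounds[-length(bounds)] - bounds[-1])),
       events = events, N0 = N0, wstart = wstart)
}

.fitPureBirth <- function(bt, window = NULL) {
  ss <- .btSuffStats(bt, window)
  lam <- ss$kEvents / ss$lineageTime
  lnL <- .pbLoglik(bt, .rateFunction("pure_birth", list(r1 = lam), .validBt(bt)),
                   window)
  list(pars = list(r1 = lam), lnL = lnL, convergence = 0L)
}

.optimMultistart <- function(fn, starts, restarts, lower = -Inf, upper = Inf) {
  best <- NULL
  for (s in seq_len(max(1L, restarts))) {
    p0 <- if (s == 1) starts else starts + rnorm(length(starts), 0, 0.7)
    o <- tryCatch(
      stats::optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e6, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimiser restarts failed")
  best
}

.fitBD <- function(bt, restarts) {
  lamHat <- .fitPureBirth(bt)$pars$r1
  nll <- function(p) {
    v <- -.bdLoglik(bt, exp(p[1]), stats::plogis(p[2]) * 0.999)
    if (!is.finite(v)) 1e10 else v
  }
  o <- .optimMultistart(nll, c(log(lamHat), -3), restarts)
  a <- stats::plogis(o$par[2]) * 0.999
  # the pure-birth boundary a = 0 is part of the parameter space
  lnL0 <- .bdLoglik(bt, .fitPureBirth(bt)$pars$r1, 0)
  if (lnL0 > -o$value) {
    list(pars = list(r1 = .fitPureBirth(bt)$pars$r1, a = 0), lnL = lnL0,
         convergence = 0L)
  } else {
    list(pars = list(r1 = exp(o$par[1]), a = a), lnL = -o$value,
         convergence = o$convergence)
  }
}

.fitDDL <- function(bt, restarts) {
  n <- .validBt(bt)
  lamHat <- .fitPureBirth(bt)$pars$r1
  nll <- function(p) {
    k <- n + 0.5 + exp(p[2])
    v <- -.pbLoglik(bt, .rateFunction("DDL", list(r1 = exp(p[1]), k = k), n))
    if (!is.finite(v)) 1e10 else v
  }
  o <- .optimMultistart(nll, c(log(lamHat), log(5 * n)), restarts)
  list(pars = list(r1 = exp(o$par[1]), k = n + 0.5 + exp(o$par[2])),
       lnL = -o$value, convergence = o$convergence)
}

.fitDDX <- function(bt, restarts) {
  n <- .validBt(bt)
  lamHat <- .fitPureBirth(bt)$pars$r1
  nll <- function(p) {
    xp <- max(min(p[2], 5), -5)
    v <- -.pbLoglik(bt, .rateFunction("DDX", list(r1 = exp(p[1]), xp = xp), n))
    if (!is.finite(v)) 1e10 else v
  }
  o <- .optimMultistart(nll, c(log(lamHat), 0), restarts,
                        lower = c(-Inf, -5), upper = c(Inf, 5))
  list(pars = list(r1 = exp(o$par[1]), xp = o$par[2]), lnL = -o$value,
       convergence = o$convergence)
}

# profile-likelihood fit of piecewise Yule with 1 or 2 shifts: per-segment
# MLE rate = events/lineage-time; candidate shifts at observed branching
# times (the profile maximum over a continuous shift age always sits at a
# branching time), ties broken toward the older age
.fitYuleShift <- function(bt, nShifts) {
  n <- .validBt(bt)
  crown <- bt[1]
  ages <- c(crown, bt[-1], 0)              # descending boundaries
  k <- length(bt) - 1L                     # events excluding crown
  # cumulative events and lineage-time older than each boundary
  counts <- seq(2L, length.out = length(ages) - 1L)
  dt <- ages[-length(ages)] - ages[-1]
  cumLT <- c(0, cumsum(counts * dt))       # lineage-time older than ages[i]
  cumEv <- c(0, seq_len(length(ages) - 1L) - 1L)
  cumEv <- pmin(cumEv, k)                  # events strictly older than ages[i]
  cand <- seq(2L, length(ages) - 1L)       # shift at bt[-1] ages
  segLnL <- function(ev, lt) ifelse(ev == 0, 0,
                                    ev * (log(ev) - log(lt)) - ev)
  if (nShifts == 1L) {
    i <- cand
    ev1 <- cumEv[i]; lt1 <- cumLT[i]
    ev2 <- k - ev1; lt2 <- cumLT[length(cumLT)] - lt1
    lnL <- lfactorial(n - 1) + segLnL(ev1, lt1) + segLnL(ev2, lt2)
    best <- which.max(lnL)
    j <- i[best]
    list(pars = list(r1 = ev1[best] / lt1[best], r2 = ev2[best] / lt2[best],
                     s1 = ages[j]),
         lnL = lnL[best], convergence = 0L)
  } else {
    pairs <- which(upper.tri(matrix(0, length(cand), length(cand))), arr.ind = TRUE)
    i1 <- cand[pairs[, 1]]; i2 <- cand[pairs[, 2]]   # i1 older (smaller index)
    keep <- ages[i1] > ages[i2]
    i1 <- i1[keep]; i2 <- i2[keep]
    ev1 <- cumEv[i1]; lt1 <- cumLT[i1]
    ev2 <- cumEv[i2] - ev1; lt2 <- cumLT[i2] - lt1
    ev3 <- k - cumEv[i2]; lt3 <- cumLT[length(cumLT)] - cumLT[i2]
    lnL <- lfactorial(n - 1) + segLnL(ev1, lt1) + segLnL(ev2, lt2) +
      segLnL(ev3, lt3)
    best <- which.max(lnL)
    list(pars = list(r1 = ev1[best] / lt1[best], r2 = ev2[best] / lt2[best],
                     r3 = ev3[best] / lt3[best],
                     s1 = ages[i1[best]], s2 = ages[i2[best]]),
         lnL = lnL[best], convergence = 0L)
  }
}

.fitWeibull <- function(bt, window, restarts) {
  ss <- .btSuffStats(bt, window)
  if (ss$kEvents < 3) stop("too few branching events inside the window")
  lamHat <- ss$kEvents / ss$lineageTime
  wstart <- ss$wstart
  nll <- function(p) {
    pars <- list(b = exp(p[1]), beta = exp(p[2]), windowStart = wstart)
    v <- -.pbLoglik(bt, .rateFunction("weibull_decline", pars, attr(bt, "n")),
                    if (is.null(window)) NULL else window)
    if (!is.finite(v)) 1e10 else v
  }
  o <- .optimMultistart(nll, c(log(1 / lamHat), 0), restarts,
                        lower = c(-12, -3), upper = c(12, 3))
  list(pars = list(b = exp(o$par[1]), beta = exp(o$par[2]),
                   windowStart = wstart),
       lnL = -o$value, convergence = o$convergence)
}

#' Fit a model set and tabulate AIC differences
#'
#' @inheritParams fitDivModel
#' @param models Model names (>= 2) in the order the table should report.
#' @param criterion `"AIC"` (table reporting) or `"AICc"`.
#' @param file Optional path: write the table as TSV.
#' @return Data frame of class `"divModelTable"` with one row per model
#'   (columns `model`, `type`, `L`, `r1`, `r2`, `a`, `k`, `xp`, `s1`, `s2`,
#'   `r3`, `AIC`, `dAIC`), `dAIC` relative to the best model.
#' @export
modelSelectionTable <- function(bt, models = c("pure_birth", "birth_death",
                                               "DDL", "DDX", "yule_2rate",
                                               "yule_3rate"),
                                criterion = c("AIC", "AICc"),
                                nObs = length(bt), file = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(length(models) >= 2)
  fits <- lapply(models, function(m) fitDivModel(bt, m, nObs = nObs))
  ic <- vapply(fits, function(f) if (criterion == "AIC") f$AIC else f$AICc,
               numeric(1))
  dIC <- ic - min(ic)
  getp <- function(f, p) if (!is.null(f$pars[[p]])) f$pars[[p]] else NA_real_
  out <- data.frame(
    model = models,
    type = unname(.modelType[models]),
    L = vapply(fits, `[[`, numeric(1), "lnL"),
    r1 = vapply(fits, getp, numeric(1), "r1"),
    r2 = vapply(fits, getp, numeric(1), "r2"),
    a = vapply(fits, getp, numeric(1), "a"),
    k = vapply(fits, getp, numeric(1), "k"),
    xp = vapply(fits, getp, numeric(1), "xp"),
    s1 = vapply(fits, getp, numeric(1), "s1"),
    s2 = vapply(fits, getp, numeric(1), "s2"),
    r3 = vapply(fits, getp, numeric(1), "r3"),
    stringsAsFactors = FALSE)
  out[[criterion]] <- ic
  out[[paste0("d", criterion)]] <- dIC
  class(out) <- c("divModelTable", "data.frame")
  attr(out, "fits") <- fits
  if (!is.null(file)) {
    utils::write.table(as.data.frame(out), file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message("wrote model-selection table (", nrow(out), " models) to ", file)
  }
  out
}

#' Simulation-based test for a shift in diversification rate
#'
#' Compares the best constant-rate against the best rate-variable model on
#' the observed tree, then calibrates the AIC(c) difference against trees
#' simulated under the constant-rate (pure-birth) MLE, conditioned on the
#' observed crown age and tip count. An assumed fraction of missing species
#' can be built into the null by simulating the inflated true richness and
#' subsampling.
#'
#' @param tree A chronogram.
#' @param constantModels,variableModels Candidate model names for the two
#'   classes.
#' @param replicates Null-simulation count (>= 100).
#' @param fractionMissing Assumed missing-species fraction f in the null.
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @param conditioning `"both"` (crown age and tip count), `"age"`, or
#'   `"taxa"`.
#' @param seed Optional seed.
#' @return A `"shiftTest"` object: observed statistic, null sample, and the
#'   pseudocount p-value `(1 + #{null >= observed}) / (1 + replicates)`.
#' @export
shiftTest <- function(tree, constantModels = "pure_birth",
                      variableModels = c("yule_2rate", "yule_3rate"),
                      replicates = 1000, fractionMissing = 0,
                      criterion = c("AICc", "AIC"),
                      conditioning = c("both", "age", "taxa"), seed = NULL) {
  criterion <- match.arg(criterion)
  conditioning <- match.arg(conditioning)
  stopifnot(replicates >= 100)
  bt <- branchingTimes(tree)
  n <- attr(bt, "n")
  crown <- bt[1]
  stat <- function(b) {
    icc <- function(m) {
      f <- fitDivModel(b, m, nObs = length(b))
      if (criterion == "AIC") f$AIC else f$AICc
    }
    min(vapply(constantModels, icc, numeric(1))) -
      min(vapply(variableModels, icc, numeric(1)))
  }
  obs <- stat(bt)
  lamHat <- .fitPureBirth(bt)$pars$r1
  .withSeed(seed, {
    nullStats <- vapply(seq_len(replicates), function(i) {
      bti <- .simulateNullBt(n, crown, lamHat, fractionMissing, conditioning)
      stat(bti)
    }, numeric(1))
    p <- (1 + sum(nullStats >= obs)) / (1 + replicates)
    structure(list(observed = obs, null = nullStats, p.value = p,
                   replicates = replicates, criterion = criterion,
                   fractionMissing = fractionMissing, lambdaHat = lamHat,
                   conditioning = conditioning, n = n, crownAge = crown),
              class = "shiftTest")
  })
}

# constant-rate null branching times under the requested conditioning,
# with optional missing-species inflation + subsampling
.simulateNullBt <- function(n, crown, lambda, fractionMissing, conditioning) {
  nTrue <- if (fractionMissing > 0) round(n / (1 - fractionMissing)) else n
  nKeep <- n
  if (conditioning == "taxa") {
    # n fixed, crown age free: forward waiting times; stop uniformly within
    # the interval during which nTrue lineages exist
    w <- rexp(nTrue - 1, lambda * seq.int(2L, nTrue))
    fwd <- cumsum(w[-length(w)])
    T <- sum(w[-length(w)]) + runif(1) * w[length(w)]
    ages <- c(T, sort(T - fwd, decreasing = TRUE))
  } else {
    if (conditioning == "age") {
      # crown age fixed, n free: draw the count, then the conditional ages
      repeat {
        nTrue <- .yuleCountGivenAge(crown, lambda)
        if (nTrue >= 3) break
      }
      nKeep <- NULL
    }
    ages <- c(crown, sort(.samplePureBirthAges(nTrue, crown, lambda, numeric(0)),
                          decreasing = TRUE))
  }
  if (fractionMissing > 0) {
    phy <- .treeFromAges(ages)
    if (!is.null(nKeep) && length(phy$tip.label) > nKeep)
      phy <- subsampleTips(phy, 1 - nKeep / length(phy$tip.label))
    return(branchingTimes(phy))
  }
  structure(ages, n = length(ages) + 1L)
}

# tip count of a Yule tree at age T from 2 crown lineages
.yuleCountGivenAge <- function(T, lambda) {
  p <- exp(-lambda * T)                    # P(one lineage leaves 1 descendant)
  2 + sum(stats::rgeom(2, p))              # geometric offspring per crown line
}

#' @export
print.shiftTest <- function(x, ...) {
  cat(sprintf(
    "Rate-shift test: observed d%s = %.3f, p = %.4g (%d null simulations%s)\n",
    x$criterion, x$observed, x$p.value, x$replicates,
    if (x$fractionMissing > 0)
      sprintf(", %d%% species assumed missing", round(100 * x$fractionMissing))
    else ""))
  invisible(x)
}

#' Weibull-decline analysis of speciation rates inside a window
#'
#' Truncates the branching times to the given window, fits a constant-rate
#' and a Weibull-shaped declining pure-birth model, and reports the
#' likelihood-ratio test with 1 degree of freedom (the shape `beta = 1`
#' recovers the constant-rate model exactly).
#'
#' @param bt Branching times.
#' @param windowStart Age (Myr) at which the window opens.
#' @return List with both fits, `beta`, `chisq`, `df`, `p.value`.
#' @export
fitWeibullWindow <- function(bt, windowStart) {
  pb <- fitDivModel(bt, "pure_birth", window = windowStart)
  wb <- fitDivModel(bt, "weibull_decline", window = windowStart)
  chisq <- max(0, 2 * (wb$lnL - pb$lnL))
  structure(list(pureBirth = pb, weibull = wb, beta = wb$pars$beta,
                 chisq = chisq, df = 1L,
                 p.value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 windowStart = windowStart),
            class = "weibullWindowFit")
}

#' @export
print.weibullWindowFit <- function(x, ...) {
  cat(sprintf(
    "Weibull decline from %.1f Ma: beta = %.3f, chi^2 = %.3f (1 d.f.), p = %.4g\n",
    x$windowStart, x$beta, x$chisq, x$p.value))
  invisible(x)
}
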