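# Mk (continuous-time Markov chain) machinery for discrete characters:
# pruning likelihood (C++ backend), rate-matrix fitting, and marginal
# ancestral-state reconstruction with ambiguous/multistate tips.

# tip partial-likelihood matrix from states given as: integer/character
# vector (NA = fully ambiguous), or a list of state sets per species
.tipPartials <- function(phy, states, stateLabels) {
  n <- length(phy$tip.label)
  k <- length(stateLabels)
  L <- matrix(0, n, k)
  if (is.list(states)) {
    states <- states[phy$tip.label]
    for (i in seq_len(n)) {
      s <- states[[i]]
      if (is.null(s) || !length(s) || all(is.na(s))) L[i, ] <- 1
      else L[i, match(s, stateLabels)] <- 1
    }
  } else {
    states <- states[phy$tip.label]
    idx <- match(states, stateLabels)
    for (i in seq_len(n)) {
      if (is.na(idx[i])) L[i, ] <- 1 else L[i, idx[i]] <- 1
    }
  }
  if (any(rowSums(L) == 0)) stop("tip state not among the model's states")
  L
}

.stateLabelsOf <- function(states) {
  if (is.list(states)) sort(unique(stats::na.omit(unlist(states))))
  else sort(unique(stats::na.omit(states)))
}

# postorder edge representation for the C++ backends
.postorderEdges <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  list(edge = phy$edge, len = phy$edge.length)
}

#' Mk log-likelihood of a discrete character on a tree
#'
#' Felsenstein pruning under an arbitrary rate matrix `Q`; tips may be
#' ambiguous (NA, or a set of occupied states for multistate codings such as
#' depth bins).
#'
#' @param phy A rooted `"phylo"` with branch lengths.
#' @param states Named vector (or list of state sets) keyed by tip label.
#' @param Q Rate matrix with `dimnames` matching the state labels.
#' @param rootPrior `"uniform"` (default), `"stationary"`, or a numeric
#'   vector of state weights.
#' @return Log-likelihood.
#' @export
mkLoglik <- function(phy, states, Q, rootPrior = "uniform") {
  labels <- rownames(Q)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(Q)))
  tipL <- .tipPartials(phy, states, labels)
  po <- .postorderEdges(phy)
  prior <- .rootPrior(rootPrior, Q)
  mk_loglik_cpp(po$edge, po$len, length(phy$tip.label), tipL, Q, prior)
}

.rootPrior <- function(rootPrior, Q) {
  k <- nrow(Q)
  if (is.numeric(rootPrior)) {
    stopifnot(length(rootPrior) == k)
    return(rootPrior / sum(rootPrior))
  }
  if (rootPrior == "uniform") return(rep(1 / k, k))
  if (rootPrior == "stationary") {
    v <- Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))])
    return(abs(v) / sum(abs(v)))
  }
  stop("unknown root prior")
}

# builds a Q from free rates under a structure: "ER" (1 rate), "SYM", "ARD"
.buildQ <- function(rates, k, model, labels = NULL) {
  Q <- matrix(0, k, k)
  off <- which(row(Q) != col(Q))
  if (model == "ER") Q[off] <- rates[1]
  else if (model == "SYM") {
    m <- matrix(0, k, k)
    m[upper.tri(m)] <- rates
    m <- m + t(m)
    Q <- m
  } else Q[off] <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (!is.null(labels)) dimnames(Q) <- list(labels, labels)
  Q
}

.nRates <- function(model, k)
  switch(model, ER = 1L, SYM = k * (k - 1L) / 2L, ARD = k * (k - 1L))

#' Fit an Mk model by maximum likelihood
#'
#' @inheritParams mkLoglik
#' @param model `"ER"` (equal rates, default), `"SYM"`, or `"ARD"`.
#' @param restarts Optimiser restarts.
#' @return List with `Q`, `lnL`, `rates`, `model`, `convergence`.
#' @export
fitMk <- function(phy, states, model = c("ER", "SYM", "ARD"),
                  rootPrior = "uniform", restarts = 3) {
  model <- match.arg(model)
  labels <- .stateLabelsOf(states)
  k <- length(labels)
  if (k < 2) stop("character is constant: no information to fit a rate matrix")
  tipL <- .tipPartials(phy, states, labels)
  po <- .postorderEdges(phy)
  nr <- .nRates(model, k)
  depth <- max(.nodeDepths(phy))
  start <- log(rep(max(k - 1, 1) / depth / k, nr))
  nll <- function(p) {
    Q <- .buildQ(exp(pmin(p, 12)), k, model, labels)
    prior <- .rootPrior(rootPrior, Q)
    v <- -mk_loglik_cpp(po$edge, po$len, length(phy$tip.label), tipL, Q, prior)
    if (!is.finite(v)) 1e10 else v
  }
  o <- .optimMultistart(nll, start, restarts, lower = -20, upper = 12)
  Q <- .buildQ(exp(o$par), k, model, labels)
  list(Q = Q, lnL = -o$value, rates = exp(o$par), model = model,
       states = labels, convergence = o$convergence)
}

#' Marginal ancestral-state reconstruction under an Mk model
#'
#' Two-pass (up/down) pruning giving the marginal posterior state
#' probabilities of every internal node; the rate matrix is estimated
#' (equal-rates by default) unless supplied. Multistate tips (e.g. depth
#' bins spanned by a species' range) enter as ambiguity over the occupied
#' states.
#'
#' @inheritParams fitMk
#' @param Q Optional fixed rate matrix (skips estimation).
#' @return An `"asrResult"`: `nodeProbs` (rows = internal nodes in ape
#'   numbering, summing to 1), `Q`, `lnL`, `states`.
#' @export
mkAsr <- function(phy, states, model = "ER", Q = NULL, rootPrior = "uniform") {
  if (is.null(Q)) {
    fit <- fitMk(phy, states, model, rootPrior)
    Q <- fit$Q; lnL <- fit$lnL; labels <- fit$states
  } else {
    labels <- rownames(Q)
    if (is.null(labels)) labels <- .stateLabelsOf(states)
    lnL <- mkLoglik(phy, states, Q, rootPrior)
  }
  k <- length(labels)
  tipL <- .tipPartials(phy, states, labels)
  phy2 <- ape::reorder.phylo(phy, "postorder")
  n <- length(phy2$tip.label)
  nn <- n + phy2$Nnode
  prior <- .rootPrior(rootPrior, Q)
  P <- lapply(seq_len(nrow(phy2$edge)), function(e) .matExp(Q, phy2$edge.length[e]))
  up <- matrix(1, nn, k)       # partial likelihood of the clade below node
  up[seq_len(n), ] <- tipL
  for (e in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[e, 1]; c <- phy2$edge[e, 2]
    msg <- as.vector(P[[e]] %*% up[c, ])
    up[p, ] <- up[p, ] * msg / max(msg)
  }
  # down pass: likelihood of everything outside the clade, given node state
  down <- matrix(1, nn, k)
  root <- n + 1L
  down[root, ] <- prior
  for (e in rev(seq_len(nrow(phy2$edge)))) {   # preorder traversal
    p <- phy2$edge[e, 1]; c <- phy2$edge[e, 2]
    sib <- phy2$edge[phy2$edge[, 1] == p, 2]
    sib <- sib[sib != c]
    sibMsg <- rep(1, k)
    for (s in sib) {
      es <- which(phy2$edge[, 2] == s)
      sibMsg <- sibMsg * as.vector(P[[es]] %*% up[s, ])
    }
    contrib <- down[p, ] * sibMsg
    down[c, ] <- as.vector(t(P[[e]]) %*% contrib)
    down[c, ] <- down[c, ] / max(down[c, ])
  }
  post <- up * down
  post <- post / rowSums(post)
  nodeProbs <- post[(n + 1L):nn, , drop = FALSE]
  colnames(nodeProbs) <- labels
  rownames(nodeProbs) <- as.character((n + 1L):nn)
  structure(list(nodeProbs = nodeProbs, Q = Q, lnL = lnL, states = labels,
                 tipPartials = tipL),
            class = "asrResult")
}

#' @export
print.asrResult <- function(x, ...) {
  cat(sprintf("Mk ancestral reconstruction: %d states (%s), lnL = %.4f\n",
              length(x$states), paste(x$states, collapse = ", "), x$lnL))
  cat("root marginal:", paste(sprintf("%s: %.3f", x$states,
                                      x$nodeProbs[1, ]), collapse = ", "), "\n")
  invisible(x)
}
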