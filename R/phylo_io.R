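#' Parse a Newick tree string
#'
#' Reads a rooted tree with branch lengths from Newick text and validates it:
#' single root, unique tip labels, non-negative branch lengths. Numeric
#' internal-node labels are interpreted as support values (the common output
#' dialect of Bayesian and bootstrap tree builders); square-bracket comments
#' are ignored.
#'
#' @param text Newick string (one tree).
#' @param lengthUnit Unit of the branch lengths: `"Myr"` for chronograms or
#'   `"subst"` for phylograms in substitutions/site. Recorded as an attribute.
#' @return An [ape::read.tree()]-style `"phylo"` object with attribute
#'   `lengthUnit`; numeric support values, when present, are available via
#'   [nodeSupport()].
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1)0.99:1,C:2);")
#' nodeSupport(tr)
parseNewick <- function(text, lengthUnit = c("Myr", "subst")) {
  lengthUnit <- match.arg(lengthUnit)
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)
  .checkBalanced(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree found in input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
    stop("branch lengths must be present and non-negative on all edges")
  attr(phy, "lengthUnit") <- lengthUnit
  phy
}

.checkBalanced <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' (string ends at position ",
         length(chars), ")")
  invisible(TRUE)
}

#' Support values stored on internal nodes
#'
#' @param phy A `"phylo"` object.
#' @return Numeric vector of length `phy$Nnode` (NA where the label is absent
#'   or non-numeric), in node order.
#' @export
nodeSupport <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(phy$node.label))
}

#' Write a tree to Newick
#'
#' @param phy A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @export
writeNewick <- function(phy, file = NULL, digits = 12) {
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  message("wrote 1 tree with ", length(phy$tip.label), " tips to ", file)
  invisible(txt)
}

# depth of every node below the root, in branch-length units
.nodeDepths <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  depth <- numeric(nn)
  phy <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(phy$edge)))
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  depth
}

#' Validate (and lightly repair) a chronogram
#'
#' Checks that the tree is ultrametric within a relative tolerance of the
#' root age. Tiny deviations (Newick round-off) are absorbed by extending
#' terminal branches so all tips sit exactly at age 0; larger deviations are
#' an error.
#'
#' @param phy A `"phylo"` object with branch lengths in Myr.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @param extend Extend tip branches to the maximum depth when the deviation
#'   is within `tol` (default `TRUE`).
#' @return The tree with class `c("chronogram", "phylo")`.
#' @export
asChronogram <- function(phy, tol = 1e-6, extend = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  if (length(phy$tip.label) < 2) stop("a chronogram needs at least 2 tips")
  depth <- .nodeDepths(phy)
  n <- length(phy$tip.label)
  tipd <- depth[seq_len(n)]
  H <- max(tipd)
  dev <- (H - min(tipd)) / H
  if (dev > tol)
    stop(sprintf(
      "tree is not ultrametric: max tip-age deviation %.3g (relative %.3g > tol %.3g)",
      H - min(tipd), dev, tol))
  if (extend && dev > 0) {
    term <- match(seq_len(n), phy$edge[, 2])
    phy$edge.length[term] <- phy$edge.length[term] + (H - tipd)
  }
  class(phy) <- unique(c("chronogram", class(phy)))
  phy
}

#' Crown (root) age of a chronogram
#' @param phy A chronogram.
#' @return Age of the root in Myr.
#' @export
rootAge <- function(phy) {
  phy <- asChronogram(phy)
  max(.nodeDepths(phy)[seq_len(length(phy$tip.label))])
}

#' Branching times of a chronogram
#'
#' Ages (Myr before present) of the internal branching events, sorted in
#' descending order with the crown age first. These are the sufficient
#' statistics for the reconstructed-process diversification likelihoods.
#'
#' @param phy A chronogram (validated with [asChronogram()]).
#' @param tol Ultrametricity tolerance passed to [asChronogram()].
#' @return Numeric vector of length `n - 1` with attributes `n` (tip count)
#'   and `ties` (TRUE when two events share an age).
#' @export
#' @examples
#' bt <- branchingTimes(parseNewick("((A:1,B:1):1,C:2);"))
branchingTimes <- function(phy, tol = 1e-6) {
  phy <- asChronogram(phy, tol = tol)
  bt <- sort(as.numeric(ape::branching.times(phy)), decreasing = TRUE)
  attr(bt, "n") <- length(phy$tip.label)
  attr(bt, "ties") <- anyDuplicated(bt) > 0
  bt
}

.validBt <- function(bt, n = NULL) {
  if (is.null(n)) n <- attr(bt, "n")
  if (is.null(n)) n <- length(bt) + 1L
  stopifnot(length(bt) == n - 1L, all(bt > 0), !is.unsorted(rev(bt)))
  n
}

#' Lineages-through-time curve
#'
#' @param phy A chronogram with at least 2 tips.
#' @return A data frame of class `"lttCurve"` with columns `age` (descending
#'   to 0) and `lineages`; the count is 2 at the crown and `n` at the present.
#' @export
lttCurve <- function(phy) {
  if (inherits(phy, "phylo") && length(phy$tip.label) < 2)
    stop("LTT curve needs at least 2 tips")
  bt <- branchingTimes(phy)
  n <- attr(bt, "n")
  out <- data.frame(age = c(bt, 0), lineages = c(seq.int(2L, n), n))
  class(out) <- c("lttCurve", "data.frame")
  out
}

#' @export
plot.lttCurve <- function(x, ..., log = "y") {
  graphics::plot(-x$age, x$lineages, type = "s", log = log,
                 xlab = "age (Ma)", ylab = "lineages", ...)
}

# contract the edges subtending the given internal nodes, preserving all
# tip depths (children inherit the contracted length)
.collapseNodes <- function(phy, nodes) {
  if (!length(nodes)) return(phy)
  n <- length(phy$tip.label)
  root <- n + 1L
  nodes <- setdiff(nodes, root)
  edge <- phy$edge
  len <- phy$edge.length
  keep <- rep(TRUE, nrow(edge))
  # remap each collapsed node's children to its nearest surviving ancestor,
  # accumulating the contracted branch lengths
  parent <- integer(max(edge))
  plen <- numeric(max(edge))
  parent[edge[, 2]] <- edge[, 1]
  plen[edge[, 2]] <- len
  dead <- rep(FALSE, max(edge))
  dead[nodes] <- TRUE
  for (e in seq_len(nrow(edge))) {
    if (dead[edge[e, 2]]) { keep[e] <- FALSE; next }
    p <- edge[e, 1]
    add <- 0
    while (dead[p]) { add <- add + plen[p]; p <- parent[p] }
    edge[e, 1] <- p
    len[e] <- len[e] + add
  }
  edge <- edge[keep, , drop = FALSE]
  len <- len[keep]
  # renumber internal nodes compactly (tips keep 1..n)
  oldInt <- sort(unique(edge[, 1]))
  newId <- integer(max(edge))
  newId[seq_len(n)] <- seq_len(n)
  newId[oldInt] <- n + seq_along(oldInt)
  out <- list(edge = cbind(newId[edge[, 1]], newId[edge[, 2]]),
              edge.length = len,
              tip.label = phy$tip.label,
              Nnode = length(oldInt))
  if (!is.null(phy$node.label))
    out$node.label <- phy$node.label[oldInt - n]
  class(out) <- "phylo"
  attributes(out)$order <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Prepare a tree and trait table for comparative analysis
#'
#' Collapses weakly supported nodes to polytomies, prunes species with
#' missing data for the focal character, and optionally re-resolves
#' polytomies with zero-length branches for likelihood methods that require
#' strictly bifurcating trees.
#'
#' @param phy A `"phylo"` object (support values on node labels if
#'   `supportThreshold > 0`).
#' @param traits Optional trait table (see [readTraitTable()]); pruned in
#'   step with the tree.
#' @param supportThreshold Nodes with numeric support strictly below this are
#'   collapsed; `0` collapses nothing. No default threshold is asserted as
#'   canonical -- choose per the support measure in use.
#' @param character Optional trait-column name; species with `NA` in that
#'   column are dropped from tree and table.
#' @param resolve Re-resolve polytomies with zero-length branches
#'   (`ape::multi2di`); recorded in the `"provenance"` attribute.
#' @return List with elements `tree` and `traits`; the tree carries a
#'   `"provenance"` attribute describing the operations applied.
#' @export
prepareTree <- function(phy, traits = NULL, supportThreshold = 0,
                        character = NULL, resolve = FALSE) {
  stopifnot(inherits(phy, "phylo"))
  prov <- character(0)
  if (supportThreshold > 0) {
    sup <- nodeSupport(phy)
    if (all(is.na(sup)))
      stop("supportThreshold > 0 but the tree carries no numeric support values")
    weak <- which(!is.na(sup) & sup < supportThreshold) + length(phy$tip.label)
    weak <- setdiff(weak, length(phy$tip.label) + 1L)  # never collapse the root
    if (length(weak)) {
      phy <- .collapseNodes(phy, weak)
      prov <- c(prov, sprintf("collapsed %d node(s) below support %g",
                              length(weak), supportThreshold))
    }
  }
  if (!is.null(character)) {
    if (is.null(traits)) stop("character pruning requested but no trait table given")
    if (!character %in% names(traits))
      stop("unknown trait column: ", character)
    miss <- traits$species[is.na(traits[[character]])]
    drop <- union(miss, setdiff(phy$tip.label, traits$species))
    drop <- intersect(drop, phy$tip.label)
    if (length(phy$tip.label) - length(drop) < 3)
      stop("pruning for '", character, "' leaves fewer than 3 tips")
    if (length(drop)) {
      phy <- ape::drop.tip(phy, drop)
      prov <- c(prov, sprintf("pruned %d species missing '%s'", length(drop), character))
    }
    traits <- traits[match(phy$tip.label, traits$species), , drop = FALSE]
  }
  if (resolve && !ape::is.binary.phylo(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 0
    prov <- c(prov, "polytomies resolved arbitrarily with zero-length branches")
  }
  attr(phy, "provenance") <- prov
  message(length(phy$tip.label), " tips retained",
          if (length(prov)) paste0(" (", paste(prov, collapse = "; "), ")"))
  list(tree = phy, traits = traits)
}

#' Read a species trait table
#'
#' Tab-separated file with one row per species and columns `species`,
#' `habitat` (organic-fall / vent / seep), `sulfur_symbiont` (0/1),
#' `methanotroph` (0/1), `symbiont_location` (intracellular / extracellular),
#' `shell_length_mm` (> 0), `depth_min_m`, `depth_max_m` (>= 0,
#' min <= max). Empty cells are missing values.
#'
#' @param file Path to the TSV file.
#' @return A validated data frame.
#' @export
readTraitTable <- function(file) {
  df <- utils::read.delim(file, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  df <- validateTraitTable(df)
  message("read ", nrow(df), " species from ", file)
  df
}

#' @rdname readTraitTable
#' @param df A data frame to validate in place.
#' @export
validateTraitTable <- function(df) {
  req <- c("species", "habitat", "sulfur_symbiont", "methanotroph",
           "symbiont_location", "shell_length_mm", "depth_min_m", "depth_max_m")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("trait table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table")
  okHab <- is.na(df$habitat) | df$habitat %in% c("organic-fall", "vent", "seep")
  if (!all(okHab)) stop("invalid habitat value(s): ",
                        paste(unique(df$habitat[!okHab]), collapse = ", "))
  okLoc <- is.na(df$symbiont_location) |
    df$symbiont_location %in% c("intracellular", "extracellular")
  if (!all(okLoc)) stop("invalid symbiont_location value(s)")
  for (b in c("sulfur_symbiont", "methanotroph"))
    if (!all(is.na(df[[b]]) | df[[b]] %in% c(0, 1)))
      stop(b, " must be 0/1/missing")
  if (any(!is.na(df$shell_length_mm) & df$shell_length_mm <= 0))
    stop("shell_length_mm must be positive")
  if (any(!is.na(df$depth_min_m) & df$depth_min_m < 0))
    stop("depths must be non-negative")
  both <- !is.na(df$depth_min_m) & !is.na(df$depth_max_m)
  if (any(df$depth_min_m[both] > df$depth_max_m[both]))
    stop("depth_min_m exceeds depth_max_m for some species")
  df
}

#' Write a trait table to TSV
#' @param df Trait table.
#' @param file Output path.
#' @export
writeTraitTable <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  message("wrote ", nrow(df), " species to ", file)
  invisible(file)
}
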