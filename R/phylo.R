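## Neighbor-joining on p-distances, nonparametric bootstrap supports,
## outgroup rooting and clade-support queries.

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Negative
#' branch-length estimates are clamped to 0 with the deficit
#' transferred to the sister edge. Ties in the Q minimisation break
#' toward the lowest (row, column) index pair, making the output
#' deterministic.
#'
#' @param d symmetric distance matrix (or \code{dist}) with unique
#'   labels, n >= 3, no NA/NaN.
#' @return an unrooted \code{phylo} tree (trifurcating root node).
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (n < 3L) hpStop("hp_config_error", "neighbor joining needs >= 3 taxa")
  if (any(is.na(d)) || any(is.nan(d))) {
    hpStop("hp_distance_error", "distance matrix contains NA/NaN")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    hpStop("hp_distance_error", "distance matrix is not symmetric")
  }
  labels <- rownames(d)
  ## each active cluster is a newick fragment
  frag <- labels
  D <- d
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ## lowest (i, j), i < j, on ties
    qmin <- min(Q)
    hits <- which(Q - qmin <= abs(qmin) * 1e-12 + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    frag <- c(frag[keep], newFrag)
    D <- D2
  }
  ## final three clusters joined at the (trifurcating) root
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nw <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(x), frag[2], fmt(y),
                frag[3], fmt(z))
  ape::read.tree(text = nw)
}

## canonical keys for the non-trivial bipartitions of a tree: for each
## internal edge, the side not containing the reference tip (the first
## tip label in sort order across the full label set), sorted and
## collapsed. Returns a character vector named by the internal node
## number the clade hangs from (root excluded).
bipartitionKeys <- function(tree, refTip = NULL) {
  labs <- tree$tip.label
  if (is.null(refTip)) refTip <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  ntip <- length(labs)
  rootNode <- ntip + 1L
  nodes <- seq(ntip + 1L, ntip + tree$Nnode)
  keys <- character(0)
  for (k in seq_along(pp)) {
    node <- nodes[k]
    if (node == rootNode) next
    clade <- labs[pp[[k]]]
    side <- if (refTip %in% clade) setdiff(labs, clade) else clade
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys[as.character(node)] <- paste(sort(side), collapse = "\r")
  }
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance + NJ tree for each replicate, and annotates each internal
#' edge of the full-data tree with the percentage of replicates whose
#' tree contains the same bipartition. Replicates in which some pair
#' has no comparable sites are skipped (and counted; a warning is
#' raised when more than 5\% are skipped).
#'
#' @param aln alignment (see \code{asAlignmentMatrix}), >= 3 sequences.
#' @param nReps number of bootstrap replicates (default 1000).
#' @param seed RNG seed; same seed, same supports.
#' @param mode deletion mode for \code{pDistanceMatrix}.
#' @return the full-data NJ tree with supports (0-100, one decimal) in
#'   \code{node.label}; attributes \code{nReps} and \code{nSkipped}.
#' @export
bootstrapSupport <- function(aln, nReps = 1000L, seed = 1L,
                             mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  m <- asAlignmentMatrix(aln)
  if (nrow(m) < 3L) hpStop("hp_config_error", "need >= 3 sequences")
  main <- njTree(pDistanceMatrix(m, mode))
  keys <- bipartitionKeys(main)
  counts <- stats::setNames(numeric(length(keys)), keys)
  nSkipped <- 0L
  withSeed(seed, {
    for (b in seq_len(nReps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      db <- tryCatch(pDistanceMatrix(m[, cols, drop = FALSE], mode),
                     hp_distance_error = function(e) NULL)
      if (is.null(db)) { nSkipped <- nSkipped + 1L; next }
      bt <- njTree(db)
      bk <- bipartitionKeys(bt, refTip = sort(rownames(m))[1])
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  used <- nReps - nSkipped
  if (nSkipped > 0.05 * nReps) {
    hpWarn("hp_bootstrap_warning", "%d of %d bootstrap replicates skipped",
           nSkipped, nReps)
  }
  support <- if (used > 0) 100 * counts / used else counts * NA
  ntip <- length(main$tip.label)
  lab <- rep("", main$Nnode)
  nodeIdx <- as.integer(names(keys)) - ntip
  lab[nodeIdx] <- sprintf("%.1f", support)
  main$node.label <- lab
  attr(main, "nReps") <- nReps
  attr(main, "nSkipped") <- nSkipped
  main
}

#' Root a tree with an outgroup
#'
#' The outgroup must form a clade (one side of a bipartition) in the
#' unrooted tree; the root is placed on the edge separating it from the
#' ingroup, and supports are preserved as edge labels.
#'
#' @param tree unrooted \code{phylo} (supports, if any, in
#'   \code{node.label}).
#' @param outgroup character vector of leaf labels.
#' @return a rooted \code{phylo}.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    hpStop("hp_config_error", "outgroup leaves not in tree: %s",
           paste(missing, collapse = ", "))
  }
  if (length(outgroup) > 1L && length(outgroup) < length(tree$tip.label) - 1L) {
    refTip <- sort(tree$tip.label)[1]
    og <- sort(outgroup)
    side <- if (refTip %in% og) sort(setdiff(tree$tip.label, og)) else og
    key <- paste(side, collapse = "\r")
    if (!(key %in% bipartitionKeys(tree))) {
      hpStop("hp_rooting_error",
             "outgroup {%s} is not monophyletic in the unrooted tree",
             paste(outgroup, collapse = ","))
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
}

#' Leaves subtended by each internal node
#'
#' @param tree a \code{phylo}.
#' @return list internal-node-number -> character vector of leaf
#'   labels.
#' @export
cladeLeafSets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- tree$tip.label
  ntip <- length(labs)
  stats::setNames(lapply(pp, function(ix) labs[ix]),
                  seq(ntip + 1L, ntip + tree$Nnode))
}

#' Support of the clade with exactly the given leaves
#'
#' @param tree a \code{phylo} with supports in \code{node.label}.
#' @param leaves character vector of leaf labels.
#' @return list: \code{isClade} (logical), \code{support} (numeric or
#'   NA; NA also when the matching node carries no numeric label, e.g.
#'   the root), \code{node} (internal node number or NA).
#' @export
cladeSupport <- function(tree, leaves) {
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) {
    hpStop("hp_config_error", "unknown leaf label(s): %s",
           paste(unknown, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  sets <- cladeLeafSets(tree)
  target <- sort(leaves)
  for (nm in names(sets)) {
    node <- as.integer(nm)
    if (node == ntip + 1L) next  # the root is not an internal edge
    if (identical(sort(sets[[nm]]), target)) {
      sup <- nodeSupport(tree, node)
      return(list(isClade = TRUE, support = sup, node = node))
    }
  }
  list(isClade = FALSE, support = NA_real_, node = NA_integer_)
}

## numeric support of an internal node, NA when absent/non-numeric
nodeSupport <- function(tree, node) {
  if (is.null(tree$node.label)) return(NA_real_)
  lab <- tree$node.label[node - length(tree$tip.label)]
  suppressWarnings(as.numeric(lab))
}

## TRUE when the tree carries no numeric supports at all
treeLacksSupports <- function(tree) {
  if (is.null(tree$node.label)) return(TRUE)
  all(is.na(suppressWarnings(as.numeric(tree$node.label))))
}
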