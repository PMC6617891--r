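## Independent oracles and generators used across the test suite.
## Each oracle is a deliberately plain re-derivation (loops, direct
## formulas) of the quantity it checks, kept free of the package's own
## implementation path.

## ---- affine-gap global alignment score, by dynamic programming ----------
## Convention: a gap run of length L costs gapOpen + gapExtend * L.
oracleAlignScore <- function(q, r, match = 2, mismatch = -3,
                             gapOpen = 5, gapExtend = 2) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in reference (consumes query)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes reference)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(gapOpen + gapExtend * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(gapOpen + gapExtend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qc[i] == rc[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExtend,
                              Ix[i, j + 1] - gapExtend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExtend,
                              Iy[i + 1, j] - gapExtend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

## ---- plain neighbor joining --------------------------------------------
## Loop-based Saitou-Nei with the same clamping convention as the
## package documents; returns a phylo via an explicit newick string.
oracleNJ <- function(d) {
  labs <- rownames(d)
  frag <- labs
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- sapply(seq_len(m), function(i) sum(D[i, ]))
    bi <- 0; bj <- 0; bq <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      qv <- (m - 2) * D[i, j] - r[i] - r[j]
      if (qv < bq - 1e-12) { bq <- qv; bi <- i; bj <- j }
    }
    li <- D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- D[bi, bj] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newf <- sprintf("(%s:%.12g,%s:%.12g)", frag[bi], max(li, 0),
                    frag[bj], max(lj, 0))
    duk <- sapply(seq_len(m), function(k) (D[bi, k] + D[bj, k] - D[bi, bj]) / 2)
    keep <- setdiff(seq_len(m), c(bi, bj))
    D2 <- matrix(0, length(keep) + 1, length(keep) + 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[length(keep) + 1, seq_along(keep)] <- duk[keep]
    D2[seq_along(keep), length(keep) + 1] <- duk[keep]
    frag <- c(frag[keep], newf)
    D <- D2
  }
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                                frag[1], max(x, 0), frag[2], max(y, 0),
                                frag[3], max(z, 0)))
}

## map bipartition -> branch length for an unrooted tree (pendant edges
## keyed by the tip label)
edgeLengthMap <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  out <- list()
  desc <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    side <- desc(ch)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    out[[key]] <- tree$edge.length[e]
  }
  out
}

expectSameTree <- function(t1, t2, tol = 1e-8) {
  m1 <- edgeLengthMap(t1); m2 <- edgeLengthMap(t2)
  expect_setequal(names(m1), names(m2))
  for (k in names(m1)) expect_equal(m1[[k]], m2[[k]], tolerance = tol)
}

## ---- per-column site classification by direct counting ------------------
oracleSiteClass <- function(m) {
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    bases <- col[col %in% c("A", "C", "G", "T")]
    if (length(bases) == 0) { out[j] <- "all_missing"; next }
    tab <- table(bases)
    if (length(tab) < 2) { out[j] <- "constant"; next }
    out[j] <- if (sum(tab >= 2) >= 2) "informative" else "variable"
  }
  out
}

## ---- hand p-distance ----------------------------------------------------
oraclePDist <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  num <- 0; den <- 0
  for (k in seq_along(av)) {
    if (av[k] %in% c("A", "C", "G", "T") && bv[k] %in% c("A", "C", "G", "T")) {
      den <- den + 1
      if (av[k] != bv[k]) num <- num + 1
    }
  }
  num / den
}

## ---- random generators --------------------------------------------------
randomAlignment <- function(n, L, pGap = 0.1, pAmb = 0.05) {
  chars <- c("A", "C", "G", "T")
  m <- matrix(sample(chars, n * L, replace = TRUE), n, L)
  mask <- matrix(runif(n * L) < pGap, n, L)
  m[mask] <- "-"
  mask2 <- matrix(runif(n * L) < pAmb, n, L)
  m[mask2] <- sample(c("N", "R", "Y", "?"), sum(mask2), replace = TRUE)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

randomDnaString <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

## additive distance matrix from a random binary tree with positive
## branch lengths; returns list(tree, d)
randomAdditiveCase <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- cophenetic(tr)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tr, d = d)
}

## leaf set under each internal node by explicit recursion
oracleCladeSets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  stats::setNames(lapply(nodes, desc), nodes)
}

## a small shared simulation, computed once per test run
sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateDataset(simConfig(seed = 424242L, nDiploidsA = 5L,
                                          nDiploidsB = 5L, nAllo = 3L,
                                          nAuto = 3L, intron5LossIn = 4L))
    }
    cache
  }
})
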