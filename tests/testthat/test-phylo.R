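test_that("three taxa solve the pairwise equations in closed form", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  m <- edgeLengthMap(tr)
  ## A's pendant edge is keyed by its complement {B, C}
  expect_equal(m[["B|C"]], 1)  # (dAB + dAC - dBC)/2
  expect_equal(m[["B"]], 2)
  expect_equal(m[["C"]], 3)
})

test_that("additive matrices are recovered exactly (topology and lengths)", {
  set.seed(51)
  for (rep in 1:30) {
    case <- randomAdditiveCase(sample(4:10, 1))
    got <- njTree(case$d)
    expect_equal(ape::dist.topo(got, ape::unroot(case$tree)), 0,
                 ignore_attr = TRUE)
    expectSameTree(got, ape::unroot(case$tree), tol = 1e-8)
  }
})

test_that("random matrices agree with a plain loop-based NJ oracle", {
  set.seed(52)
  for (rep in 1:20) {
    n <- 5
    x <- matrix(runif(n * n), n, n)
    d <- (x + t(x)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expectSameTree(njTree(d), oracleNJ(d), tol = 1e-9)
  }
})

test_that("nj input is validated", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
  expect_error(njTree(d2), class = "hp_config_error")
  d3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(d3), class = "hp_distance_error")
})

test_that("bootstrap supports are reproducible and sensible", {
  set.seed(53)
  m <- randomAlignment(6, 120, pGap = 0, pAmb = 0)
  ## make s1/s2 identical and distant from the rest
  m[2, ] <- m[1, ]
  t1 <- bootstrapSupport(m, nReps = 60, seed = 9)
  t2 <- bootstrapSupport(m, nReps = 60, seed = 9)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  cs <- cladeSupport(rootWithOutgroup(t1, "s6"), c("s1", "s2"))
  expect_true(cs$isClade)
  expect_equal(cs$support, 100)
})

test_that("bootstrap supports are invariant to leaf order", {
  set.seed(54)
  m <- randomAlignment(6, 100, pGap = 0, pAmb = 0)
  perm <- sample(nrow(m))
  t1 <- bootstrapSupport(m, nReps = 40, seed = 5)
  t2 <- bootstrapSupport(m[perm, ], nReps = 40, seed = 5)
  k1 <- vapply(cladeLeafSets(t1), function(x) paste(sort(x), collapse = "|"),
               character(1))
  s1 <- stats::setNames(t1$node.label, k1)
  k2 <- vapply(cladeLeafSets(t2), function(x) paste(sort(x), collapse = "|"),
               character(1))
  s2 <- stats::setNames(t2$node.label, k2)
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 0)
  expect_equal(s1[shared], s2[shared])
})

test_that("simulated clades outscore random bipartitions on average", {
  sim <- sharedSim()
  aln <- sim$truth$alignment
  tr <- bootstrapSupport(aln, nReps = 60, seed = 31)
  rooted <- rootWithOutgroup(tr, c("OUT01__1", "OUT02__1"))
  poolA <- sim$truth$perSequence$seq_id[sim$truth$perSequence$pool == "A"]
  trueSup <- cladeSupport(rooted, poolA)
  expect_true(trueSup$isClade)
  expect_gt(trueSup$support, 90)
  ## a random mixed-pool leaf set is not a clade at all
  set.seed(55)
  fake <- c(sample(poolA, 2),
            sample(sim$truth$perSequence$seq_id[
              sim$truth$perSequence$pool == "B"], 2))
  expect_false(cladeSupport(rooted, fake)$isClade)
})

test_that("outgroup rooting places and validates the root", {
  tr <- ape::read.tree(text = "((A:1,B:1)80:1,(C:1,D:1)90:1,E:2);")
  r1 <- rootWithOutgroup(tr, "E")
  expect_true(ape::is.rooted(r1))
  expect_true(cladeSupport(r1, c("A", "B"))$support == 80)

  r2 <- rootWithOutgroup(tr, c("A", "B"))
  expect_true(ape::is.rooted(r2))
  expect_equal(cladeSupport(r2, c("C", "D"))$support, 90)

  expect_error(rootWithOutgroup(tr, c("A", "C")), class = "hp_rooting_error")
  expect_error(rootWithOutgroup(tr, "Z"), class = "hp_config_error")
})

test_that("clade support queries agree with brute-force clade enumeration", {
  tr <- ape::read.tree(text = "((A,B)90,(C,D)80);")
  expect_equal(cladeSupport(tr, c("A", "B"))$support, 90)
  expect_false(cladeSupport(tr, c("A", "B", "C", "D"))$isClade)
  expect_error(cladeSupport(tr, "missing"), class = "hp_config_error")

  set.seed(56)
  for (rep in 1:10) {
    t <- ape::rtree(7)
    sets <- oracleCladeSets(t)
    rootNode <- length(t$tip.label) + 1
    for (nm in names(sets)) {
      got <- cladeSupport(t, sets[[nm]])
      if (as.integer(nm) == rootNode) {
        expect_false(got$isClade)
      } else {
        expect_true(got$isClade)
        expect_equal(got$node, as.integer(nm))
      }
    }
    ## random non-clade subsets
    for (k in 1:5) {
      ss <- sample(t$tip.label, 3)
      isClade <- any(vapply(sets, function(x) setequal(x, ss), logical(1)))
      expect_equal(cladeSupport(t, ss)$isClade, isClade)
    }
  }
})
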