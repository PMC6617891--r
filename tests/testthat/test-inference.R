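mkGenotype <- function(ids, labels, ind = "X") {
  genotypeIndividual(data.frame(seq_id = ids, label = labels), ind)
}

test_that("homoeolog monophyly follows the subtree leaf-set definition", {
  tr <- ape::read.tree(text = "((x1,x2),(y1,y2));")
  expect_equal(homoeologMonophyly(tr, "x1"), "single_copy")
  expect_equal(homoeologMonophyly(tr, c("x1", "x2")), "monophyletic")
  expect_equal(homoeologMonophyly(tr, c("x1", "y1")), "non_monophyletic")
  expect_error(homoeologMonophyly(tr, c("x1", "zz")),
               class = "hp_config_error")
})

test_that("monophyly agrees with a brute-force subtree oracle on random trees", {
  set.seed(61)
  for (rep in 1:10) {
    tr <- ape::rtree(8)
    sets <- oracleCladeSets(tr)
    for (k in 1:12) {
      ss <- sample(tr$tip.label, sample(2:5, 1))
      isClade <- any(vapply(sets, function(x) setequal(x, ss), logical(1)))
      got <- homoeologMonophyly(tr, ss)
      expect_equal(got == "monophyletic", isClade,
                   label = paste(sort(ss), collapse = ","))
    }
  }
})

test_that("major-clade assignment respects exemplar MRCAs", {
  tr <- ape::read.tree(
    text = "(((a1,a2)95,(a3,q1)90)99,(b1,(b2,q2)92)97,out);")
  tr <- rootWithOutgroup(tr, "out")
  ex <- cladeExemplars(I = c("a1", "a2", "a3"), II = c("b1", "b2"))
  asg <- assignMajorClades(tr, c("a1", "q1", "q2", "b2", "out"), ex)
  expect_equal(asg$clade, c("I", "I", "II", "II", "unassigned"))
  expect_error(assignMajorClades(tr, "a1",
                                 cladeExemplars(I = "zzz", II = "b1")),
               class = "hp_config_error")
  expect_error(cladeExemplars(I = c("a1", "a2"), II = c("a2", "b1")),
               class = "hp_config_error")
})

test_that("origin calls follow the clade-placement criterion", {
  tr <- ape::read.tree(
    text = "(((a1:1,a2:1)95:1,(a3:1,p1:1)90:1)99:1,(b1:1,(b2:1,p2:1)92:1)97:3,out:5);")
  tr <- rootWithOutgroup(tr, "out")
  ex <- cladeExemplars(I = c("a1", "a2", "a3"), II = c("b1", "b2"))

  ## one copy in each major clade, all supports high -> allopolyploid
  allo <- classifyOrigin(tr, mkGenotype(c("p1", "p2"), c("V1A", "V1B")),
                         ex, supportMin = 70, ploidy = 4L)
  expect_equal(verdict(allo), "ALLOPOLYPLOID_PATTERN")
  expect_gte(allo@minSeparatingSupport, 70)

  ## the same placement in a diploid is reported as hybrid-pattern
  hyb <- classifyOrigin(tr, mkGenotype(c("p1", "p2"), c("V1A", "V1B")),
                        ex, supportMin = 70, ploidy = 2L)
  expect_equal(verdict(hyb), "ALLOPOLYPLOID_PATTERN")
  expect_equal(hyb@patternLabel, "hybrid-pattern")

  ## sister copies -> autopolyploid
  auto <- classifyOrigin(tr, mkGenotype(c("a1", "a2"), c("V1A", "V1A")),
                         ex, supportMin = 70, ploidy = 4L)
  expect_equal(verdict(auto), "AUTOPOLYPLOID_PATTERN")

  ## single copy -> uninformative
  single <- classifyOrigin(tr, mkGenotype("p1", "V1A"), ex, ploidy = 4L)
  expect_equal(verdict(single), "UNINFORMATIVE")

  ## support gating: raising the threshold turns the call uninformative
  strict <- classifyOrigin(tr, mkGenotype(c("p1", "p2"), c("V1A", "V1B")),
                           ex, supportMin = 99.5, ploidy = 4L)
  expect_equal(verdict(strict), "UNINFORMATIVE")
})

test_that("a support-free tree triggers unsupported-tree mode", {
  tr <- ape::read.tree(text = "(((a1,p1),a2),(b1,(b2,p2)),out);")
  tr <- rootWithOutgroup(tr, "out")
  ex <- cladeExemplars(I = c("a1", "a2"), II = c("b1", "b2"))
  cl <- classifyOrigin(tr, mkGenotype(c("p1", "p2"), c("V1A", "V1B")), ex,
                       ploidy = 4L)
  expect_equal(verdict(cl), "ALLOPOLYPLOID_PATTERN")
  expect_match(cl@rationale, "unsupported-tree")
  expect_true(is.na(cl@minSeparatingSupport))
})

test_that("allopolyploid is never called on a monophyletic copy set", {
  set.seed(62)
  for (rep in 1:15) {
    tr <- ape::rtree(10)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
    sets <- oracleCladeSets(tr)
    ## pick a random true clade as the individual's copies
    cl <- sets[[sample(seq_along(sets), 1)]]
    if (length(cl) < 2 || length(cl) > 8) next
    ex <- cladeExemplars(I = setdiff(tr$tip.label, cl)[1], II = cl[1])
    g <- mkGenotype(cl, rep("V1A", length(cl)))
    got <- classifyOrigin(tr, g, ex, supportMin = 0, ploidy = 4L)
    expect_equal(verdict(got), "AUTOPOLYPLOID_PATTERN")
  }
})

test_that("verdicts are invariant to leaf rotations of the tree", {
  tr <- ape::read.tree(
    text = "(((a1,a2)95,(a3,p1)90)99,(b1,(b2,p2)92)97,out);")
  tr <- rootWithOutgroup(tr, "out")
  ex <- cladeExemplars(I = c("a1", "a2", "a3"), II = c("b1", "b2"))
  g <- mkGenotype(c("p1", "p2"), c("V1A", "V1B"))
  v1 <- verdict(classifyOrigin(tr, g, ex, ploidy = 4L))
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  v2 <- verdict(classifyOrigin(rot, g, ex, ploidy = 4L))
  expect_equal(v1, v2)
})

test_that("origin reports join metadata and display labels", {
  tr <- ape::read.tree(
    text = "(((a1,a2)95,(a3,p1)90)99,(b1,(b2,p2)92)97,out);")
  tr <- rootWithOutgroup(tr, "out")
  ex <- cladeExemplars(I = c("a1", "a2", "a3"), II = c("b1", "b2"))
  calls <- list(classifyOrigin(tr, mkGenotype(c("p1", "p2"),
                                              c("V1A", "V1B"), "IND7"),
                               ex, ploidy = 4L))
  meta <- data.frame(individual_id = "IND7", taxon_name = "R. simulatus",
                     section = "Malachobatus", subsection = "",
                     ploidy = 4L, accessions = "")
  rep <- originReport(calls, meta)
  expect_equal(rep$individual_id, "IND7")
  expect_equal(rep$labels, "1a+1b")
  expect_equal(rep$taxon_name, "R. simulatus")
  expect_equal(rep$verdict, "ALLOPOLYPLOID_PATTERN")
})
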