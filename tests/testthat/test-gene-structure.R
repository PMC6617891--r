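ref <- syntheticReference()
refSeq <- as.character(refSequence(ref))
refSegs <- geneSegments(ref)

## apply an edit (deletion/insertion) to the reference sequence at a
## 0-based position, returning the edited string
delAt <- function(s, start0, len) {
  paste0(substr(s, 1, start0), substr(s, start0 + len + 1, nchar(s)))
}
insAt <- function(s, start0, piece) {
  paste0(substr(s, 1, start0), piece, substr(s, start0 + 1, nchar(s)))
}
segRow <- function(kind, index) {
  refSegs[refSegs$kind == kind & refSegs$index == index, ]
}

test_that("projecting the reference onto itself reproduces its own model", {
  m <- projectExonBoundaries(refSeq, ref)
  expect_equal(geneSegments(m)$start, refSegs$start)
  expect_equal(geneSegments(m)$end, refSegs$end)
  expect_equal(intronLengths(m), intronLengths(refModel(ref)))
  expect_false(any(geneSegments(m)$lost))
  ## idempotence: re-projecting the projected model's sequence changes nothing
  m2 <- projectExonBoundaries(refSeq, ref)
  expect_equal(geneSegments(m2), geneSegments(m))
})

test_that("segments always tile the sequence", {
  set.seed(31)
  for (rep in 1:5) {
    ## random interior deletions in two introns
    q <- refSeq
    i4 <- segRow("intron", 4)
    q <- delAt(q, i4$start + 50, sample(20:120, 1))
    m <- projectExonBoundaries(q, ref)
    seg <- geneSegments(m)
    expect_equal(seg$start[1], 0L)
    expect_equal(seg$end[nrow(seg)], nchar(q))
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
  }
})

test_that("an interior intron-4 deletion shifts downstream segments exactly", {
  i4 <- segRow("intron", 4)
  q <- delAt(refSeq, i4$start + 100, 100)
  m <- projectExonBoundaries(q, ref)
  il <- intronLengths(m)
  expect_equal(il[["4"]], intronLengths(refModel(ref))[["4"]] - 100L)
  seg <- geneSegments(m)
  after <- seg$start[seg$start > i4$start]
  refAfter <- refSegs$start[refSegs$start > i4$start]
  expect_equal(after, refAfter - 100L)
})

test_that("a spliced-out fifth intron is flagged lost with zero length", {
  i5 <- segRow("intron", 5)
  q <- delAt(refSeq, i5$start, i5$end - i5$start)
  m <- projectExonBoundaries(q, ref)
  seg <- geneSegments(m)
  lost <- seg[seg$kind == "intron" & seg$index == 5, ]
  expect_true(lost$lost)
  expect_equal(intronLengths(m)[["5"]], 0L)
  ## other introns unaffected
  expect_equal(intronLengths(m)[c("3", "4", "6", "7")],
               intronLengths(refModel(ref))[c("3", "4", "6", "7")])
})

test_that("boundaries snap to GT within the window after a small shift", {
  ## delete 3 bp spanning the intron-4 5' boundary (removes its GT);
  ## the projector should either snap to a nearby GT or flag the
  ## boundary, never crash, and keep the model tiling
  i4 <- segRow("intron", 4)
  q <- delAt(refSeq, i4$start - 1, 3)
  m <- suppressWarnings(projectExonBoundaries(q, ref))
  seg <- geneSegments(m)
  expect_equal(seg$end[nrow(seg)], nchar(q))
  got <- seg[seg$kind == "intron" & seg$index == 4, ]
  if (isTRUE(got$canon5)) {
    expect_equal(substr(q, got$start + 1, got$start + 2), "GT")
  }
})

test_that("queries with insufficient coverage raise a projection error", {
  expect_error(projectExonBoundaries(substr(refSeq, 1, 300), ref),
               class = "hp_projection_error")
})

test_that("the unmodified reference is not a pseudogene", {
  m <- projectExonBoundaries(refSeq, ref)
  pg <- detectPseudogene(refSeq, m, ref)
  expect_false(pg@internalStop)
  expect_false(pg@frameshift)
  expect_false(isPseudogene(pg))
  expect_equal(nrow(pg@exonicIndels), 0L)
})

test_that("a 1 bp exonic deletion is a frameshift, confirmed by translation", {
  e5 <- segRow("exon", 5)
  q <- delAt(refSeq, e5$start + 30, 1)
  m <- projectExonBoundaries(q, ref)
  pg <- detectPseudogene(q, m, ref)
  expect_true(pg@frameshift)
  expect_true(isPseudogene(pg))
  expect_equal(pg@exonicIndels$delta[pg@exonicIndels$exonIndex == 5], -1L)
  ## independent translation oracle: translate the frameshifted exon
  ## concatenation directly and compare the stop finding
  seg <- geneSegments(m)
  ex <- seg[seg$kind == "exon", ]
  cds <- paste(substring(q, ex$start + 1, ex$end), collapse = "")
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                      seq(3, nchar(cds), 3))
  oracleStops <- which(codons %in% c("TAA", "TAG", "TGA"))
  expect_equal(pg@stopPositions, as.integer(oracleStops))
  expect_equal(pg@internalStop, length(oracleStops) > 0)
})

test_that("an in-frame TAA insertion gives a stop without frameshift", {
  e6 <- segRow("exon", 6)
  offset <- 3 * 10  # a codon boundary within exon 6 (frame offset 0,
                    # upstream exon lengths are multiples of 3 + 7+150+96
  upstream <- sum((refSegs$end - refSegs$start)[refSegs$kind == "exon" &
                                                  refSegs$index < 6])
  phase <- (3 - upstream %% 3) %% 3
  pos <- e6$start + phase + offset
  q <- insAt(refSeq, pos, "TAA")
  m <- projectExonBoundaries(q, ref)
  pg <- detectPseudogene(q, m, ref)
  expect_false(pg@frameshift)
  expect_true(pg@internalStop)
  expect_true(isPseudogene(pg))
})

test_that("intron lengths of constructed models follow the construction", {
  expect_equal(intronLengths(refModel(ref)),
               c(`3` = 80L, `4` = 440L, `5` = 90L, `6` = 80L, `7` = 85L))
  expect_equal(sum(exonLengths(refModel(ref))), 516L)
})
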