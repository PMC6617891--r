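test_that("identical configs give byte-identical output", {
  cfg <- simConfig(seed = 99, nDiploidsA = 3, nDiploidsB = 3,
                   nAllo = 2, nAuto = 2)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth$alignment, s2$truth$alignment)
  expect_identical(s1$meta, s2$meta)
  ## and the generator leaves the caller's RNG stream untouched
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(simulateDataset(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the null model reproduces the ancestor exactly", {
  cfg <- simConfig(seed = 1, nDiploidsA = 3, nDiploidsB = 2, nAllo = 0,
                   nAuto = 0, stemDepth = 0, crownDepth = 0,
                   intronIndelRate = 0, intron4DeletionBp = 100,
                   polyploidTipDepth = 0, pseudogeneRate = 0,
                   includeOutgroup = FALSE)
  sim <- simulateDataset(cfg)
  ref <- cfg$ref
  refStr <- as.character(refSequence(ref))
  for (id in grep("^dA", names(sim$sequences), value = TRUE)) {
    expect_equal(as.character(sim$sequences[[id]]), refStr)
  }
  ## typing through the full projection path: pool A is all V1A
  for (id in grep("^dA", names(sim$sequences), value = TRUE)) {
    m <- projectExonBoundaries(as.character(sim$sequences[[id]]), ref)
    expect_equal(as.character(classifyVariant(m, ref)), "V1A")
  }
})

test_that("structural truth holds exactly when intron indels are off", {
  cfg <- simConfig(seed = 5, nDiploidsA = 3, nDiploidsB = 3, nAllo = 2,
                   nAuto = 2, intronIndelRate = 0, pseudogeneRate = 0,
                   intron5LossIn = 2L)
  sim <- simulateDataset(cfg)
  ref <- cfg$ref
  refI4 <- intronLengths(refModel(ref))[["4"]]
  tr <- truthReport(sim$truth)
  for (k in seq_len(nrow(tr))) {
    m <- projectExonBoundaries(as.character(sim$sequences[[tr$seq_id[k]]]),
                               ref)
    il <- intronLengths(m)
    if (tr$pool[k] == "A" || tr$pool[k] == "outgroup") {
      expect_equal(il[["4"]], refI4)
    } else {
      expect_equal(il[["4"]], refI4 - cfg$intron4DeletionBp)
    }
    if (tr$variant_truth[k] == "1c") expect_equal(il[["5"]], 0L)
  }
})

test_that("every allopolyploid carries one copy from each pool", {
  sim <- sharedSim()
  tr <- truthReport(sim$truth)
  allo <- tr[tr$origin_mode == "allopolyploid", ]
  for (ind in unique(allo$individual_id)) {
    expect_setequal(allo$pool[allo$individual_id == ind], c("A", "B"))
  }
  auto <- tr[tr$origin_mode == "autopolyploid", ]
  for (ind in unique(auto$individual_id)) {
    expect_equal(length(unique(auto$pool[auto$individual_id == ind])), 1L)
    expect_equal(sum(auto$individual_id == ind), 2L)
  }
})

test_that("the truth alignment degaps to the emitted sequences", {
  sim <- sharedSim()
  aln <- sim$truth$alignment
  for (id in rownames(aln)) {
    row <- aln[id, ]
    expect_equal(paste(row[row != "-"], collapse = ""),
                 as.character(sim$sequences[[id]]))
  }
  ## generating tree leaves match emitted sequences
  expect_setequal(sim$truth$tree$tip.label, names(sim$sequences))
})

test_that("pseudogene truth matches detection when only exonic indels occur", {
  cfg <- simConfig(seed = 17, nDiploidsA = 4, nDiploidsB = 4, nAllo = 3,
                   nAuto = 3, intronIndelRate = 0, pseudogeneRate = 0.5)
  sim <- simulateDataset(cfg)
  ref <- cfg$ref
  tr <- truthReport(sim$truth)
  expect_gt(sum(tr$pseudogene), 0)
  for (k in seq_len(nrow(tr))) {
    m <- projectExonBoundaries(as.character(sim$sequences[[tr$seq_id[k]]]),
                               ref)
    pg <- detectPseudogene(as.character(sim$sequences[[tr$seq_id[k]]]),
                           m, ref)
    expect_equal(isPseudogene(pg), tr$pseudogene[k],
                 label = tr$seq_id[k])
  }
})

test_that("truth report round-trips through delimited text", {
  sim <- sharedSim()
  tr <- truthReport(sim$truth)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tr, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back, tr)
  ## exactly one truth row per emitted sequence
  expect_setequal(tr$seq_id, names(sim$sequences))
  expect_equal(anyDuplicated(tr$seq_id), 0L)
})

test_that("infeasible configurations are rejected", {
  expect_error(simConfig(intron4DeletionBp = 10000), class = "hp_config_error")
  expect_error(simConfig(stemDepth = -1), class = "hp_config_error")
  expect_error(simConfig(crownDepth = 0.5, stemDepth = 0.1),
               class = "hp_config_error")
  expect_error(simConfig(intron5LossIn = 99L), class = "hp_config_error")
})

test_that("between-pool divergence tracks the JC69 expectation", {
  ## quick single-replicate sanity; the full Monte-Carlo check lives in
  ## the acceptance suite
  cfg <- simConfig(seed = 23, nDiploidsA = 4, nDiploidsB = 4, nAllo = 0,
                   nAuto = 0, pseudogeneRate = 0)
  sim <- simulateDataset(cfg)
  keep <- !sim$truth$columns$protected &
    startsWith(ifelse(is.na(sim$truth$columns$segment), "x",
                      sim$truth$columns$segment), "i")
  aln <- sim$truth$alignment[, keep, drop = FALSE]
  A <- grep("^dA", rownames(aln), value = TRUE)
  B <- grep("^dB", rownames(aln), value = TRUE)
  d <- pDistanceMatrix(aln)
  obs <- mean(d[A, B])
  expected <- 0.75 * (1 - exp(-8 * cfg$stemDepth / 3))
  expect_lt(abs(obs - expected), 0.03)
})
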