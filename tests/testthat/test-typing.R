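ref <- syntheticReference()

## a GeneModel with prescribed intron-4/5 lengths, otherwise reference-like
modelWithIntrons <- function(i4, i5, lost5 = i5 == 0) {
  seg <- geneSegments(ref)
  lens <- seg$end - seg$start
  lens[seg$kind == "intron" & seg$index == 4] <- i4
  lens[seg$kind == "intron" & seg$index == 5] <- i5
  seg$start <- c(0L, cumsum(lens)[-length(lens)])
  seg$end <- cumsum(lens)
  seg$lost[seg$kind == "intron" & seg$index == 5] <- lost5
  geneModel("m", sum(lens), seg, frameOffset = 0L)
}

test_that("variant classification follows the intron-length rule", {
  cfg <- typingConfig()
  expect_equal(as.character(classifyVariant(modelWithIntrons(450, 90), ref, cfg)), "V1A")
  expect_equal(as.character(classifyVariant(modelWithIntrons(220, 90), ref, cfg)), "V1B")
  expect_equal(as.character(classifyVariant(modelWithIntrons(220, 0), ref, cfg)), "V1C")
  ## the combination unseen in real data
  expect_equal(as.character(classifyVariant(modelWithIntrons(450, 0), ref, cfg)),
               "UNCLASSIFIED")
  ## observed boundary lengths: 403-484 bp long variant, 191-249 short
  for (L in c(403, 484)) {
    expect_equal(as.character(classifyVariant(modelWithIntrons(L, 90), ref, cfg)), "V1A")
  }
  for (L in c(191, 249)) {
    expect_equal(as.character(classifyVariant(modelWithIntrons(L, 90), ref, cfg)), "V1B")
  }
  ## the intron-4 deficit is reported alongside
  lab <- classifyVariant(modelWithIntrons(180, 90), ref, cfg)
  expect_equal(attr(lab, "intron4Deficit"), 440 - 180)
})

test_that("classification is a pure function of intron lengths", {
  ## models differing only in exonic content (here: same segment table,
  ## classification never reads residues) yield identical labels
  m <- modelWithIntrons(250, 85)
  l1 <- classifyVariant(m, ref)
  l2 <- classifyVariant(m, ref, typingConfig(tau4 = 300))
  expect_equal(as.character(l1), as.character(l2))
  ## a truncated model lacking intron 4/5 annotation is a typing error
  seg <- geneSegments(ref)
  seg <- seg[1:3, ]  # exon 3, intron 3, exon 4 only
  m2 <- geneModel("x", max(seg$end), seg, 0L)
  expect_error(classifyVariant(m2, ref), class = "hp_typing_error")
})

test_that("genotyping aggregates labels per individual", {
  g <- genotypeIndividual(data.frame(seq_id = "s1", label = "V1A"), "I1")
  expect_equal(g$labels, "V1A")
  expect_equal(g$distinct, 1L)

  g3 <- genotypeIndividual(
    data.frame(seq_id = c("s1", "s2", "s3"),
               label = c("V1A", "V1B", "V1C")), "I2")
  expect_equal(g3$labels, c("V1A", "V1B", "V1C"))
  expect_equal(g3$distinct, 3L)

  g2 <- genotypeIndividual(
    data.frame(seq_id = c("s1", "s2"), label = c("V1A", "V1A")), "I3")
  expect_equal(g2$labels, c("V1A", "V1A"))
  expect_equal(g2$distinct, 1L)

  expect_error(genotypeIndividual(data.frame(), "I4"),
               class = "hp_typing_error")
})

test_that("indel cataloguing merges maximal shared-gap runs", {
  gapless <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(nrow(catalogueIndels(gapless)), 0L)

  m <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  m[1, 4:6] <- "-"
  ev <- catalogueIndels(m)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 3L)      # 0-based half-open [3, 6)
  expect_equal(ev$end, 6L)
  expect_equal(ev$length, 3L)
  expect_equal(ev$polarity, "deletion")  # one gapped of four
  expect_equal(ev$member_ids, "s1")

  ## adjacent runs with different member sets stay separate events
  m2 <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  m2[1, 3:4] <- "-"
  m2[c(1, 2), 5:6] <- "-"
  ev2 <- catalogueIndels(m2)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$length, c(2L, 2L))
  expect_equal(ev2$member_ids, c("s1", "s1;s2"))

  ## majority gapped -> the residue carriers hold an insertion
  m3 <- matrix("A", 4, 6, dimnames = list(paste0("s", 1:4), NULL))
  m3[1:3, 2:3] <- "-"
  expect_equal(catalogueIndels(m3)$polarity, "insertion")
})

test_that("cross-tabulation counts partition the genotyped individuals", {
  expect_equal(nrow(crossTabulate(list(), data.frame())), 0L)

  sim <- sharedSim()
  tr <- truthReport(sim$truth)
  gts <- lapply(split(tr, tr$individual_id), function(df)
    genotypeIndividual(data.frame(
      seq_id = df$seq_id,
      label = c(`1a` = "V1A", `1b` = "V1B", `1c` = "V1C",
                outgroup = "V1A")[df$variant_truth]),
      df$individual_id[1]))
  ct <- crossTabulate(gts, sim$meta)
  expect_equal(sum(ct$n_individuals), length(gts))
  ## every allopolyploid contributes a two-variant combination
  allo <- ct[ct$section == "Malachobatus" & grepl("\\+", ct$variants), ]
  nAllo <- sum(sim$truth$perIndividual$origin_mode == "allopolyploid")
  expect_equal(sum(allo$n_individuals), nAllo)

  gOrphan <- list(genotypeIndividual(
    data.frame(seq_id = "q", label = "V1A"), "nobody"))
  expect_error(crossTabulate(gOrphan, sim$meta), class = "hp_join_error")
})
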