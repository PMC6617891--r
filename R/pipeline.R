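## End-to-end orchestration: annotate -> screen -> type -> stats ->
## tree -> infer -> report.

#' Pipeline configuration
#'
#' Inputs may be given as paths or as in-memory objects. Tree building
#' requires an alignment (this package consumes alignments, it does not
#' produce them) or an externally computed tree; the simulator provides
#' a gap-tracked truth alignment for fully self-contained runs.
#'
#' @param sequences unaligned sequences: DNAStringSet or FASTA path.
#' @param meta metadata: data.frame or path.
#' @param ref a \linkS4class{ReferenceModel} (default: the synthetic
#'   reference).
#' @param alignment optional alignment (matrix/DNAStringSet/FASTA path)
#'   whose rows cover the sequence ids.
#' @param tree optional externally computed tree (phylo or Newick
#'   path); when supplied, tree construction is skipped.
#' @param typing a \code{typingConfig()}.
#' @param orthology an \code{orthologyConfig()}.
#' @param nBootstrap bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @param supportMin support floor for origin inference (default 70).
#' @param deletionMode "pairwise" or "complete" for distances.
#' @param exemplars optional \code{cladeExemplars()}; default derives
#'   them from typed diploids.
#' @param outgroup leaf labels used for rooting (NULL: detect a leaf
#'   of an individual whose metadata section is "Outgroup").
#' @param treeSites "all" or "exons" (exon columns only; requires the
#'   alignment column metadata from the simulator).
#' @param alignmentColumns optional data.frame with a \code{segment}
#'   column per alignment column (as in \code{SimTruth$columns}).
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(sequences, meta, ref = syntheticReference(),
                           alignment = NULL, tree = NULL,
                           typing = typingConfig(),
                           orthology = orthologyConfig(),
                           nBootstrap = 1000L, seed = 1L, supportMin = 70,
                           deletionMode = c("pairwise", "complete"),
                           exemplars = NULL, outgroup = NULL,
                           treeSites = c("all", "exons"),
                           alignmentColumns = NULL) {
  structure(list(sequences = sequences, meta = meta, ref = ref,
                 alignment = alignment, tree = tree, typing = typing,
                 orthology = orthology, nBootstrap = as.integer(nBootstrap),
                 seed = seed, supportMin = supportMin,
                 deletionMode = match.arg(deletionMode),
                 exemplars = exemplars, outgroup = outgroup,
                 treeSites = match.arg(treeSites),
                 alignmentColumns = alignmentColumns),
            class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Stages: exon/intron annotation by boundary projection; amino-acid
#' identity orthology screen; structural-variant typing and pseudogene
#' detection; per-variant alignment statistics; NJ tree with bootstrap
#' supports (or an imported tree); per-individual origin calls; and
#' cross-tabulation. Every input sequence appears exactly once in the
#' typing table with status "typed", "screened-out" or "failed".
#'
#' @param cfg a \code{pipelineConfig()}.
#' @return list of class "RunReport": \code{typingTable},
#'   \code{genotypes}, \code{stats} (per variant group),
#'   \code{tree} (combined, rooted when an outgroup is available),
#'   \code{variantTrees}, \code{originCalls}, \code{originTable},
#'   \code{crossTab}, \code{indels}, \code{warnings},
#'   \code{provenance}.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  warningsLog <- character(0)
  logW <- function(w) warningsLog <<- c(warningsLog, conditionMessage(w))

  seqs <- if (is.character(cfg$sequences)) readFastaSeqs(cfg$sequences)
          else cfg$sequences
  if (length(seqs) == 0L) hpStop("hp_config_error", "empty sequence set")
  meta <- if (is.character(cfg$meta)) readSampleMetadata(cfg$meta)
          else cfg$meta
  ref <- cfg$ref
  seqIds <- names(seqs)
  ind <- mapSequencesToIndividuals(seqIds, meta)

  ## annotate + screen + type
  rows <- vector("list", length(seqIds))
  models <- list(); reports <- list()
  for (k in seq_along(seqIds)) {
    id <- seqIds[k]
    sq <- as.character(seqs[[k]])
    row <- data.frame(seq_id = id, individual_id = ind[[id]],
                      status = "typed", label = NA_character_,
                      intron4_len = NA_integer_, intron5_len = NA_integer_,
                      identity = NA_real_, pseudogene = NA,
                      frameshift = NA, internal_stop = NA)
    res <- withCallingHandlers(
      tryCatch({
        m <- projectExonBoundaries(sq, ref, seqId = id)
        pg <- detectPseudogene(sq, m, ref)
        ## the amino-acid identity screen is meaningless on a
        ## frameshifted translation; detected pseudogenes keep their
        ## structural label and bypass the screen
        scr <- if (isTRUE(pg@frameshift) || pg@undetermined) {
          list(pass = NA, identity = NA_real_, alignedAa = 0L,
               status = "skipped")
        } else {
          orthologyScreen(sq, m, ref, cfg$orthology)
        }
        list(m = m, pg = pg, scr = scr)
      }, hp_error = function(e) e),
      warning = function(w) { logW(w); invokeRestart("muffleWarning") })
    if (inherits(res, "condition")) {
      row$status <- "failed"
      rows[[k]] <- row
      next
    }
    row$identity <- res$scr$identity
    if (isFALSE(res$scr$pass)) {
      row$status <- "screened-out"
      rows[[k]] <- row
      next
    }
    pg <- res$pg
    il <- intronLengths(res$m)
    row$label <- as.character(classifyVariant(res$m, ref, cfg$typing))
    row$intron4_len <- il[["4"]]
    row$intron5_len <- il[["5"]]
    row$pseudogene <- isPseudogene(pg)
    row$frameshift <- pg@frameshift
    row$internal_stop <- pg@internalStop
    models[[id]] <- res$m
    reports[[id]] <- pg
    rows[[k]] <- row
  }
  typingTable <- do.call(rbind, rows)

  typed <- typingTable[typingTable$status == "typed", , drop = FALSE]
  ## outgroup sequences are kept for rooting even when the orthology
  ## screen rejects them: a distant outgroup legitimately fails an
  ## ortholog-identity criterion but still anchors the root
  outInds <- meta$individual_id[meta$section == "Outgroup"]
  outSeqIds <- typingTable$seq_id[typingTable$individual_id %in% outInds &
                                    typingTable$status != "failed"]
  genotypes <- lapply(split(typed, typed$individual_id), function(df)
    genotypeIndividual(df, df$individual_id[1]))

  ## alignment-dependent stages
  alnM <- NULL
  if (!is.null(cfg$alignment)) {
    alnM <- if (is.character(cfg$alignment) && !is.matrix(cfg$alignment))
      asAlignmentMatrix(readFastaSeqs(cfg$alignment, aligned = TRUE))
    else asAlignmentMatrix(cfg$alignment)
    alnM <- alnM[intersect(rownames(alnM), union(typed$seq_id, outSeqIds)), ,
                 drop = FALSE]
  }

  statsOut <- list(); indels <- NULL; variantTrees <- list()
  if (!is.null(alnM)) {
    ## statistics exclude the outgroup (variation within the study group)
    ingroup <- typed[!(typed$individual_id %in% outInds), , drop = FALSE]
    grp <- split(ingroup$seq_id, ingroup$label)
    dropEmpty <- function(m) m[, colSums(m != "-") > 0L, drop = FALSE]
    statsOut[["all"]] <- summaryStats(
      dropEmpty(alnM[intersect(rownames(alnM), ingroup$seq_id), , drop = FALSE]))
    for (g in names(grp)) {
      sub <- dropEmpty(alnM[grp[[g]], , drop = FALSE])
      statsOut[[variantDisplay(g)]] <- summaryStats(sub)
      if (length(grp[[g]]) >= 3L) {
        variantTrees[[variantDisplay(g)]] <-
          njTree(pDistanceMatrix(sub, cfg$deletionMode))
      }
    }
    indels <- catalogueIndels(alnM)
  }

  ## tree
  tree <- NULL
  if (!is.null(cfg$tree)) {
    tree <- if (is.character(cfg$tree)) readNewickTree(cfg$tree) else cfg$tree
  } else if (!is.null(alnM) && nrow(alnM) >= 3L) {
    treeAln <- alnM
    if (cfg$treeSites == "exons") {
      if (is.null(cfg$alignmentColumns)) {
        hpStop("hp_config_error",
               "treeSites='exons' requires alignmentColumns metadata")
      }
      keep <- startsWith(cfg$alignmentColumns$segment %||% "", "e")
      treeAln <- alnM[, keep, drop = FALSE]
    }
    tree <- withCallingHandlers(
      bootstrapSupport(treeAln, nReps = cfg$nBootstrap, seed = cfg$seed,
                       mode = cfg$deletionMode),
      warning = function(w) { logW(w); invokeRestart("muffleWarning") })
  }

  ## root and infer
  originCalls <- list(); originTable <- NULL; rootedTree <- NULL
  if (!is.null(tree)) {
    og <- cfg$outgroup
    if (is.null(og)) {
      outInds <- meta$individual_id[meta$section == "Outgroup"]
      og <- typed$seq_id[typed$individual_id %in% outInds]
      og <- intersect(og, tree$tip.label)
      if (!length(og)) og <- NULL
    }
    rootedTree <- if (!is.null(og)) {
      tryCatch(rootWithOutgroup(tree, og),
               hp_rooting_error = function(e) {
                 ## non-monophyletic outgroup set: fall back to the
                 ## first outgroup leaf alone
                 logW(e)
                 rootWithOutgroup(tree, og[1])
               })
    } else tree
    exemplars <- cfg$exemplars %||%
      tryCatch(autoExemplars(typed[typed$seq_id %in% rootedTree$tip.label, ],
                             meta),
               hp_error = function(e) { logW(e); NULL })
    if (!is.null(exemplars)) {
      inTree <- vapply(genotypes, function(g)
        all(g$perSequence$seq_id %in% rootedTree$tip.label), logical(1))
      plMap <- stats::setNames(meta$ploidy, meta$individual_id)
      originCalls <- lapply(genotypes[inTree], function(g)
        classifyOrigin(rootedTree, g, exemplars,
                       supportMin = cfg$supportMin,
                       ploidy = plMap[[g$individualId]]))
      originTable <- originReport(originCalls, meta)
    }
  }

  crossTab <- crossTabulate(genotypes, meta)

  structure(list(
    typingTable = typingTable, genotypes = genotypes, models = models,
    pseudogeneReports = reports, stats = statsOut, indels = indels,
    tree = rootedTree %||% tree, variantTrees = variantTrees,
    originCalls = originCalls, originTable = originTable,
    crossTab = crossTab, warnings = warningsLog,
    provenance = list(seed = cfg$seed, nBootstrap = cfg$nBootstrap,
                      supportMin = cfg$supportMin,
                      deletionMode = cfg$deletionMode,
                      nSequences = length(seqIds),
                      package = as.character(utils::packageVersion("homoeoPhy")),
                      timestamp = NA)
  ), class = "RunReport")
}

#' Summary tables in the style of a sequence-variation table and a
#' variant-by-section presence matrix
#'
#' @param report a "RunReport".
#' @return list: \code{variationTable} (one row per region: all
#'   sequences, each variant, each variant's intron 4 when column
#'   metadata is present) and \code{presenceMatrix} (sections x
#'   variant combinations, individual counts).
#' @export
makeFiguresTables <- function(report) {
  stopifnot(inherits(report, "RunReport"))
  statRow <- function(region, s, nInd) {
    data.frame(region = region, n_individuals = nInd,
               n_sequences = s$nSequences,
               length_range = sprintf("%d-%d", s$lengthRange[["min"]],
                                      s$lengthRange[["max"]]),
               aligned_length = s$alignedLength,
               variable_sites = s$variableSites,
               variable_pct = round(s$variablePct, 2),
               informative_sites = s$informativeSites,
               informative_pct = round(s$informativePct, 2))
  }
  typed <- report$typingTable[report$typingTable$status == "typed", ,
                              drop = FALSE]
  rows <- list()
  for (nm in names(report$stats)) {
    nInd <- if (nm == "all") length(unique(typed$individual_id))
            else length(unique(typed$individual_id[
              variantDisplay(typed$label) == nm]))
    rows[[nm]] <- statRow(nm, report$stats[[nm]], nInd)
  }
  variationTable <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), n_individuals = integer(),
               n_sequences = integer(), length_range = character(),
               aligned_length = integer(), variable_sites = integer(),
               variable_pct = numeric(), informative_sites = integer(),
               informative_pct = numeric())
  rownames(variationTable) <- NULL

  ct <- report$crossTab
  presenceMatrix <- if (nrow(ct)) {
    stats::xtabs(n_individuals ~ section + variants, data = ct)
  } else {
    matrix(integer(0), 0L, 0L)
  }
  list(variationTable = variationTable, presenceMatrix = presenceMatrix)
}

#' Write the pieces of a run report to a directory
#'
#' @param report a "RunReport".
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$typingTable, file.path(dir, "typing.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$originTable)) {
    utils::write.table(report$originTable, file.path(dir, "origin_calls.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(report$crossTab, file.path(dir, "cross_tabulation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$indels)) {
    utils::write.table(report$indels, file.path(dir, "indels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$tree)) {
    writeNewickTree(report$tree, file.path(dir, "tree.nwk"))
  }
  for (nm in names(report$variantTrees)) {
    writeNewickTree(report$variantTrees[[nm]],
                    file.path(dir, sprintf("tree_%s.nwk", nm)))
  }
  tabs <- makeFiguresTables(report)
  utils::write.table(tabs$variationTable, file.path(dir, "variation_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
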