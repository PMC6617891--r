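## Structural-variant classification (1a/1b/1c), per-individual
## genotyping, indel cataloguing and genotype cross-tabulation.

#' Typing thresholds for the structural-variant classifier
#'
#' @param tau4 absolute intron-4 length (bp) below which intron 4
#'   counts as "short" (default 300; the observed long-variant lengths,
#'   403-484 bp, and short-variant lengths, 191-249 bp, are separated
#'   by this value).
#' @param deficitMin minimum shortfall vs the reference intron-4 length
#'   (bp) recorded as a corroborating statistic, not used by the
#'   primary rule (default 260).
#' @param intron5LostMax intron-5 lengths at or below this count as
#'   lost (default 20, matching the projection's minimum intron
#'   length).
#' @return a list of class "TypingConfig".
#' @export
typingConfig <- function(tau4 = 300, deficitMin = 260, intron5LostMax = 20) {
  if (tau4 <= 0 || deficitMin <= 0 || intron5LostMax <= 0) {
    hpStop("hp_config_error", "typing thresholds must be positive")
  }
  structure(list(tau4 = tau4, deficitMin = deficitMin,
                 intron5LostMax = intron5LostMax),
            class = "TypingConfig")
}

#' Classify a sequence into structural variant 1a / 1b / 1c
#'
#' The rule is a pure function of intron lengths: a short fourth intron
#' (length < \code{tau4}) together with a lost fifth intron gives V1C;
#' a short fourth intron alone gives V1B; otherwise V1A. The unseen
#' combination (long intron 4 with lost intron 5) is UNCLASSIFIED.
#'
#' @param model the query's \linkS4class{GeneModel}.
#' @param ref the \linkS4class{ReferenceModel} (for the intron-4
#'   deficit statistic).
#' @param cfg a \code{typingConfig()}.
#' @return character(1) in {"V1A","V1B","V1C","UNCLASSIFIED"}, with
#'   attribute \code{intron4Deficit}.
#' @export
classifyVariant <- function(model, ref, cfg = typingConfig()) {
  il <- intronLengths(model)
  if (!all(c("4", "5") %in% names(il))) {
    hpStop("hp_typing_error", "model lacks intron 4 and/or intron 5 annotation")
  }
  i4 <- il[["4"]]; i5 <- il[["5"]]
  refI4 <- intronLengths(refModel(ref))[["4"]]
  short4 <- i4 < cfg$tau4
  lost5 <- i5 <= cfg$intron5LostMax
  label <- if (short4 && lost5) "V1C"
           else if (short4) "V1B"
           else if (!lost5) "V1A"
           else "UNCLASSIFIED"
  structure(label, intron4Deficit = refI4 - i4)
}

#' Genotype one individual from its typed sequences
#'
#' @param typed data.frame with columns \code{seq_id}, \code{label}
#'   (and optionally \code{pseudogene}), all belonging to the
#'   individual.
#' @param individualId the individual's id.
#' @return list of class "GenotypeRecord": \code{individualId},
#'   \code{labels} (multiset, character vector), \code{distinct}
#'   (count of distinct labels), \code{perSequence} (the input table).
#' @export
genotypeIndividual <- function(typed, individualId) {
  if (is.null(typed) || nrow(typed) == 0L) {
    hpStop("hp_typing_error", "no typed sequences for individual %s", individualId)
  }
  labels <- sort(typed$label)
  structure(list(individualId = individualId, labels = labels,
                 distinct = length(unique(labels)), perSequence = typed),
            class = "GenotypeRecord")
}

#' Catalogue alignment indels as maximal shared-gap events
#'
#' Maximal runs of gap columns with an identical set of gapped
#' sequences are merged into one event. Polarity is defined against the
#' column-majority state: the event is an insertion when the sequences
#' carrying residues are the minority, a deletion otherwise (ties count
#' as deletions).
#'
#' @param aln an alignment as a character matrix (rows = sequences,
#'   rownames = ids) or an aligned DNAStringSet.
#' @return data.frame with one row per event: \code{start}, \code{end}
#'   (0-based half-open column range), \code{length}, \code{polarity},
#'   \code{n_members}, \code{member_ids} (";"-joined gapped sequences).
#' @export
catalogueIndels <- function(aln) {
  m <- asAlignmentMatrix(aln)
  n <- nrow(m)
  gap <- m == "-"
  keys <- apply(gap, 2, function(col) paste(which(col), collapse = ","))
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      polarity = character(), n_members = integer(),
                      member_ids = character())
  keep <- keys != ""
  if (!any(keep)) return(empty)
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- runs$values != ""
  members <- strsplit(runs$values[sel], ",", fixed = TRUE)
  nm <- lengths(members)
  data.frame(
    start = starts[sel] - 1L,
    end = ends[sel],
    length = runs$lengths[sel],
    polarity = ifelse(n - nm < nm, "insertion", "deletion"),
    n_members = nm,
    member_ids = vapply(members, function(ix)
      paste(rownames(m)[as.integer(ix)], collapse = ";"), character(1))
  )
}

#' Cross-tabulate genotypes by section and ploidy
#'
#' @param genotypes list of GenotypeRecord.
#' @param meta metadata data.frame (see \code{readSampleMetadata}).
#' @return data.frame (section, ploidy, variants, n_individuals) whose
#'   counts partition the genotyped individuals.
#' @export
crossTabulate <- function(genotypes, meta) {
  if (length(genotypes) == 0L) {
    return(data.frame(section = character(), ploidy = integer(),
                      variants = character(), n_individuals = integer()))
  }
  ids <- vapply(genotypes, `[[`, character(1), "individualId")
  orphans <- setdiff(ids, meta$individual_id)
  if (length(orphans)) {
    hpStop("hp_join_error", "individual(s) missing from metadata: %s",
           paste(orphans, collapse = ", "))
  }
  combo <- vapply(genotypes, function(g)
    paste(sort(unique(variantDisplay(g$labels))), collapse = "+"), character(1))
  mrow <- match(ids, meta$individual_id)
  df <- data.frame(section = meta$section[mrow],
                   ploidy = meta$ploidy[mrow],
                   variants = combo)
  agg <- stats::aggregate(list(n_individuals = rep(1L, nrow(df))),
                          by = df[c("section", "ploidy", "variants")],
                          FUN = sum)
  agg[order(agg$section, agg$ploidy, agg$variants), , drop = FALSE]
}

## V1A -> "1a" display form used in tables.
variantDisplay <- function(x) {
  map <- c(V1A = "1a", V1B = "1b", V1C = "1c", UNCLASSIFIED = "unclassified")
  unname(ifelse(x %in% names(map), map[x], x))
}
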