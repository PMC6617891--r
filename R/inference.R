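## The duplicated-gene clade-placement criterion: gene copies of an
## autopolyploid should be each other's closest relatives in the gene
## tree, whereas an allopolyploid's homoeologs fall in different major
## clades.

#' Define major clades by exemplar sequences
#'
#' @param ... named character vectors, e.g.
#'   \code{cladeExemplars(I = c("a1","a2"), II = c("b1","b2"))}.
#' @return named list of class "CladeExemplars" (sets must be
#'   disjoint).
#' @export
cladeExemplars <- function(...) {
  ex <- list(...)
  if (length(ex) == 1L && is.list(ex[[1]]) && is.null(names(ex))) ex <- ex[[1]]
  if (is.null(names(ex)) || any(!nzchar(names(ex)))) {
    hpStop("hp_config_error", "clade exemplar sets must be named")
  }
  all <- unlist(ex, use.names = FALSE)
  if (any(duplicated(all))) {
    hpStop("hp_config_error", "exemplar sets must be disjoint (duplicated: %s)",
           paste(unique(all[duplicated(all)]), collapse = ", "))
  }
  structure(ex, class = "CladeExemplars")
}

#' Monophyly of one individual's gene copies
#'
#' @param tree rooted \code{phylo}.
#' @param seqIds the individual's sequence leaves.
#' @return "single_copy", "monophyletic" or "non_monophyletic".
#' @export
homoeologMonophyly <- function(tree, seqIds) {
  missing <- setdiff(seqIds, tree$tip.label)
  if (length(missing)) {
    hpStop("hp_config_error", "leaf/leaves not in tree: %s",
           paste(missing, collapse = ", "))
  }
  if (length(seqIds) == 1L) return("single_copy")
  mrca <- ape::getMRCA(tree, seqIds)
  below <- cladeLeafSets(tree)[[as.character(mrca)]]
  if (setequal(below, seqIds)) "monophyletic" else "non_monophyletic"
}

## Resolve exemplars to (MRCA node, descendant leaf set, support) per clade.
resolveExemplars <- function(tree, exemplars) {
  sets <- cladeLeafSets(tree)
  lapply(exemplars, function(ids) {
    missing <- setdiff(ids, tree$tip.label)
    if (length(missing)) {
      hpStop("hp_config_error", "exemplar(s) not in tree: %s",
             paste(missing, collapse = ", "))
    }
    if (length(ids) == 1L) {
      return(list(node = match(ids, tree$tip.label), leaves = ids,
                  support = NA_real_))
    }
    mrca <- ape::getMRCA(tree, ids)
    list(node = mrca, leaves = sets[[as.character(mrca)]],
         support = nodeSupport(tree, mrca))
  })
}

#' Assign sequences to major clades
#'
#' A sequence is assigned to clade K iff it descends from the MRCA of
#' K's exemplars and from no other clade's MRCA; sequences under
#' nested or overlapping MRCAs, or under none, are "unassigned".
#'
#' @param tree rooted \code{phylo}.
#' @param seqIds sequences to assign.
#' @param exemplars a \code{cladeExemplars()} object.
#' @return data.frame (seq_id, clade, clade_support).
#' @export
assignMajorClades <- function(tree, seqIds, exemplars) {
  res <- resolveExemplars(tree, exemplars)
  member <- vapply(res, function(cl) seqIds %in% cl$leaves,
                   logical(length(seqIds)))
  if (length(seqIds) == 1L) member <- matrix(member, nrow = 1L)
  nIn <- rowSums(member)
  clade <- rep("unassigned", length(seqIds))
  sup <- rep(NA_real_, length(seqIds))
  one <- nIn == 1L
  if (any(one)) {
    which1 <- apply(member[one, , drop = FALSE], 1, which)
    clade[one] <- names(res)[which1]
    sup[one] <- vapply(res[which1], `[[`, numeric(1), "support")
  }
  data.frame(seq_id = seqIds, clade = clade, clade_support = sup)
}

#' Call the polyploid-origin pattern of one individual
#'
#' Single-copy individuals are UNINFORMATIVE. Individuals whose copies
#' are monophyletic get AUTOPOLYPLOID_PATTERN. Non-monophyletic copies
#' assigned to >= 2 distinct major clades whose defining edges all meet
#' the support threshold get ALLOPOLYPLOID_PATTERN (with the minimum
#' separating support recorded); anything else is UNINFORMATIVE with a
#' rationale. When the tree carries no supports at all, support gating
#' is disabled and the rationale notes "unsupported-tree mode". For a
#' diploid (ploidy 2) an allopolyploid-style placement is displayed as
#' "hybrid-pattern".
#'
#' @param tree rooted, support-annotated \code{phylo}.
#' @param genotype a GenotypeRecord (see \code{genotypeIndividual});
#'   its \code{perSequence$seq_id} must be leaves of \code{tree}.
#' @param exemplars a \code{cladeExemplars()} object.
#' @param supportMin bootstrap-percent floor for "well-supported"
#'   separating clades (default 70).
#' @param ploidy the individual's ploidy (NA allowed).
#' @return an \linkS4class{OriginCall}.
#' @export
classifyOrigin <- function(tree, genotype, exemplars, supportMin = 70,
                           ploidy = NA_integer_) {
  seqIds <- genotype$perSequence$seq_id
  labels <- genotype$perSequence$label
  mono <- homoeologMonophyly(tree, seqIds)
  assign <- assignMajorClades(tree, seqIds, exemplars)
  copies <- data.frame(seqId = seqIds, label = labels,
                       clade = assign$clade,
                       cladeSupport = assign$clade_support)
  unsupported <- treeLacksSupports(tree)
  mkCall <- function(verdict, minSup, rationale) {
    patt <- verdict
    if (verdict == "ALLOPOLYPLOID_PATTERN" && !is.na(ploidy) && ploidy == 2L) {
      patt <- "hybrid-pattern"
    }
    new("OriginCall", individualId = genotype$individualId,
        verdict = verdict, patternLabel = patt, copies = copies,
        minSeparatingSupport = minSup, rationale = rationale)
  }
  if (mono == "single_copy") {
    return(mkCall("UNINFORMATIVE", NA_real_, "single gene copy"))
  }
  if (mono == "monophyletic") {
    return(mkCall("AUTOPOLYPLOID_PATTERN", NA_real_,
                  "gene copies are each other's closest relatives"))
  }
  clades <- unique(copies$clade[copies$clade != "unassigned"])
  if (length(clades) < 2L) {
    return(mkCall("UNINFORMATIVE", NA_real_,
                  "copies non-monophyletic but not placed in two major clades"))
  }
  if (unsupported) {
    return(mkCall("ALLOPOLYPLOID_PATTERN", NA_real_,
                  paste("copies in distinct major clades;",
                        "unsupported-tree mode (no supports on tree)")))
  }
  ## separating support for a copy pair in different clades: the
  ## best-supported edge whose bipartition places one copy together
  ## with its clade's exemplars on one side and the other copy with
  ## its exemplars on the other
  sets <- cladeLeafSets(tree)
  pairSup <- numeric(0)
  n <- nrow(copies)
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      ca <- copies$clade[a]; cb <- copies$clade[b]
      if (ca == "unassigned" || cb == "unassigned" || ca == cb) next
      g1 <- intersect(c(copies$seqId[a], exemplars[[ca]]), tree$tip.label)
      g2 <- intersect(c(copies$seqId[b], exemplars[[cb]]), tree$tip.label)
      pairSup <- c(pairSup, maxSeparatingSupport(tree, sets, g1, g2))
    }
  }
  minSup <- suppressWarnings(min(pairSup, na.rm = TRUE))
  if (!is.finite(minSup)) minSup <- NA_real_
  if (!is.na(minSup) && minSup >= supportMin) {
    return(mkCall("ALLOPOLYPLOID_PATTERN", minSup,
                  sprintf("copies in clades {%s}, min separating support %.1f",
                          paste(clades, collapse = ","), minSup)))
  }
  mkCall("UNINFORMATIVE", minSup,
         "separating clade support below threshold")
}

## Maximum support among internal edges separating leaf group g1 from
## leaf group g2 in a rooted, support-annotated tree.
maxSeparatingSupport <- function(tree, sets, g1, g2) {
  ntip <- length(tree$tip.label)
  best <- NA_real_
  for (nm in names(sets)) {
    node <- as.integer(nm)
    if (node == ntip + 1L) next
    cl <- sets[[nm]]
    sep <- (all(g1 %in% cl) && !any(g2 %in% cl)) ||
           (all(g2 %in% cl) && !any(g1 %in% cl))
    if (!sep) next
    s <- nodeSupport(tree, node)
    if (!is.na(s) && (is.na(best) || s > best)) best <- s
  }
  best
}

#' Tabular report of origin calls
#'
#' @param calls list of \linkS4class{OriginCall}.
#' @param meta metadata data.frame (optional; adds taxon/section/ploidy
#'   columns).
#' @return data.frame, one row per individual.
#' @export
originReport <- function(calls, meta = NULL) {
  rows <- lapply(calls, function(cl) {
    data.frame(
      individual_id = cl@individualId,
      n_copies = nrow(cl@copies),
      labels = paste(variantDisplay(sort(cl@copies$label)), collapse = "+"),
      clades = paste(cl@copies$clade, collapse = "+"),
      verdict = cl@verdict,
      pattern = cl@patternLabel,
      min_separating_support = cl@minSeparatingSupport,
      rationale = cl@rationale
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    mrow <- match(out$individual_id, meta$individual_id)
    out <- cbind(out[1], taxon_name = meta$taxon_name[mrow],
                 section = meta$section[mrow], ploidy = meta$ploidy[mrow],
                 out[-1])
  }
  rownames(out) <- NULL
  out
}

#' Derive clade exemplars from typed sequences
#'
#' Major clade I is anchored by the sequences typed as the long
#' intron-4 variant (V1A), clade II by those typed V1B or V1C,
#' mirroring the correspondence between the gene tree's two major
#' clades and the structural variants: each clade comprises all
#' sequences of its variant, from diploids and polyploids alike.
#' With \code{scope = "diploid"} only diploid sequences anchor the
#' clades.
#'
#' @param typingTable data.frame (seq_id, individual_id, label).
#' @param meta metadata data.frame with ploidy.
#' @param excludeSections sections never used as exemplars (default
#'   "Outgroup": outgroup leaves must not anchor an ingroup clade).
#' @param scope "all" (default) or "diploid".
#' @return a \code{cladeExemplars()} object.
#' @export
autoExemplars <- function(typingTable, meta, excludeSections = "Outgroup",
                          scope = c("all", "diploid")) {
  scope <- match.arg(scope)
  mrow <- match(typingTable$individual_id, meta$individual_id)
  pl <- meta$ploidy[mrow]
  sect <- meta$section[mrow]
  keep <- !(sect %in% excludeSections)
  if (scope == "diploid") keep <- keep & !is.na(pl) & pl == 2L
  tab <- typingTable[keep, , drop = FALSE]
  eI <- tab$seq_id[tab$label == "V1A"]
  eII <- tab$seq_id[tab$label %in% c("V1B", "V1C")]
  if (!length(eI) || !length(eII)) {
    hpStop("hp_config_error",
           "cannot derive exemplars: need sequences of both variant groups")
  }
  cladeExemplars(I = eI, II = eII)
}
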