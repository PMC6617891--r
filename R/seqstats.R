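## Alignment statistics, uncorrected p-distances and the amino-acid
## identity orthology screen. Gaps ('-'), '?' and IUPAC ambiguity codes
## all count as missing data.

#' Coerce to an alignment character matrix
#'
#' @param x aligned DNAStringSet, named character vector of equal
#'   length strings, or a character matrix (returned unchanged apart
#'   from validation).
#' @return character matrix, rows = sequences (rownames = ids),
#'   columns = alignment columns.
#' @export
asAlignmentMatrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    ch <- as.character(x)
    if (length(unique(nchar(ch))) != 1L) {
      hpStop("hp_alignment_error", "sequences have unequal lengths")
    }
    m <- do.call(rbind, strsplit(ch, "", fixed = TRUE))
    rownames(m) <- names(x) %||% paste0("seq", seq_along(ch))
  }
  if (any(duplicated(rownames(m)))) {
    hpStop("hp_validation_error", "duplicate sequence ids in alignment")
  }
  toupper(m)
}

#' Classify alignment columns
#'
#' A column is \emph{variable} iff at least two distinct unambiguous
#' bases occur in it, and \emph{parsimony informative} iff at least two
#' distinct bases each occur in at least two sequences. Columns with no
#' unambiguous base at all are \emph{all_missing}; informative columns
#' are reported as "informative" (a subset of variable).
#'
#' @param aln alignment (see \code{asAlignmentMatrix}).
#' @return character vector, one of "all_missing", "constant",
#'   "variable", "informative" per column.
#' @export
siteClassification <- function(aln) {
  m <- asAlignmentMatrix(aln)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  present <- counts > 0
  ge2 <- counts >= 2
  nStates <- rowSums(present)
  out <- rep("constant", ncol(m))
  out[nStates == 0] <- "all_missing"
  out[nStates >= 2] <- "variable"
  out[rowSums(ge2) >= 2] <- "informative"
  out
}

#' Alignment summary statistics
#'
#' @param aln alignment (see \code{asAlignmentMatrix}).
#' @return list of class "SeqStats": \code{nSequences},
#'   \code{alignedLength}, \code{lengthRange} (min/max ungapped bp),
#'   \code{variableSites}, \code{variablePct},
#'   \code{informativeSites}, \code{informativePct} (percentages of the
#'   aligned length; formatted to two decimals on printing).
#' @export
summaryStats <- function(aln) {
  m <- asAlignmentMatrix(aln)
  cls <- siteClassification(m)
  ungapped <- rowSums(m != "-" & m != "?")
  variable <- sum(cls %in% c("variable", "informative"))
  informative <- sum(cls == "informative")
  structure(list(
    nSequences = nrow(m),
    alignedLength = ncol(m),
    lengthRange = c(min = min(ungapped), max = max(ungapped)),
    variableSites = variable,
    variablePct = 100 * variable / ncol(m),
    informativeSites = informative,
    informativePct = 100 * informative / ncol(m)
  ), class = "SeqStats")
}

#' @export
print.SeqStats <- function(x, ...) {
  cat(sprintf(
    "SeqStats: %d sequences, %d aligned columns, lengths %d-%d bp\n",
    x$nSequences, x$alignedLength, x$lengthRange[["min"]],
    x$lengthRange[["max"]]))
  cat(sprintf("  variable sites: %d (%.2f%%); parsimony informative: %d (%.2f%%)\n",
              x$variableSites, x$variablePct, x$informativeSites,
              x$informativePct))
  invisible(x)
}

#' Uncorrected p-distance between two aligned rows
#'
#' Mismatches divided by compared sites; positions missing (gap, '?' or
#' ambiguity) in either row are excluded.
#'
#' @param a,b equal-length aligned sequences (character strings or
#'   character vectors of single residues).
#' @return the distance in [0, 1].
#' @export
pDistance <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "", fixed = TRUE)[[1]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "", fixed = TRUE)[[1]] else toupper(b)
  if (length(av) != length(bv)) {
    hpStop("hp_alignment_error", "rows have unequal length")
  }
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) hpStop("hp_distance_error", "no comparable sites")
  sum(av[ok] != bv[ok]) / sum(ok)
}

#' Uncorrected p-distance matrix
#'
#' @param aln alignment (see \code{asAlignmentMatrix}).
#' @param mode "pairwise" (default) excludes missing data per pair;
#'   "complete" first drops every column containing any missing state.
#' @return symmetric matrix with zero diagonal and attribute
#'   \code{deletionMode}.
#' @export
pDistanceMatrix <- function(aln, mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  m <- asAlignmentMatrix(aln)
  if (mode == "complete") {
    valid <- m %in% c("A", "C", "G", "T")
    dim(valid) <- dim(m)
    m <- m[, colSums(!valid) == 0L, drop = FALSE]
    if (ncol(m) == 0L) hpStop("hp_distance_error", "no complete columns")
  }
  ind <- lapply(c("A", "C", "G", "T"), function(b) (m == b) * 1)
  validM <- Reduce(`+`, ind)
  comparable <- tcrossprod(validM)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  if (any(comparable[upper.tri(comparable)] == 0)) {
    hpStop("hp_distance_error", "sequence pair with no comparable sites")
  }
  d <- 1 - matches / comparable
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "deletionMode") <- mode
  d
}

#' Orthology-screen configuration
#'
#' @param identityMin minimum amino-acid identity fraction (default
#'   0.90).
#' @param minAlignedAa minimum number of aligned (both non-gap)
#'   residues (default 100).
#' @return list of class "OrthologyConfig".
#' @export
orthologyConfig <- function(identityMin = 0.90, minAlignedAa = 100) {
  if (identityMin <= 0 || identityMin > 1) {
    hpStop("hp_config_error", "identityMin must be in (0, 1]")
  }
  structure(list(identityMin = identityMin, minAlignedAa = minAlignedAa),
            class = "OrthologyConfig")
}

#' Amino-acid identity orthology screen
#'
#' Translates the query's and the reference's exonic concatenations,
#' aligns the proteins globally (BLOSUM62, affine gaps) and computes
#' identity = matches / aligned columns where both carry a residue.
#' Pass iff identity >= \code{identityMin} and aligned residue columns
#' >= \code{minAlignedAa}.
#'
#' @param query query sequence (character or DNAString).
#' @param model the query's \linkS4class{GeneModel}.
#' @param ref the \linkS4class{ReferenceModel}.
#' @param cfg an \code{orthologyConfig()}.
#' @return list: \code{pass} (logical, NA when skipped),
#'   \code{identity}, \code{alignedAa}, \code{status} ("ok"/"skipped").
#' @export
orthologyScreen <- function(query, model, ref, cfg = orthologyConfig()) {
  aaOf <- function(sq, mdl) {
    cds <- exonicSequence(sq, mdl)
    off <- (3L - frameOffset(mdl)) %% 3L
    coding <- substr(cds, off + 1L, nchar(cds))
    n <- nchar(coding) %/% 3L
    if (n < 1L) return(NULL)
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(coding, 1L, n * 3L)),
      if.fuzzy.codon = "X"))
  }
  qa <- aaOf(query, model)
  ra <- aaOf(as.character(refSequence(ref)), refModel(ref))
  if (is.null(qa) || is.null(ra)) {
    hpWarn("hp_screen_warning", "untranslatable query %s; screen skipped",
           model@seqId)
    return(list(pass = NA, identity = NA_real_, alignedAa = 0L,
                status = "skipped"))
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(qa), subject = Biostrings::AAString(ra),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  aq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ar <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- aq != "-" & ar != "-"
  alignedAa <- sum(both)
  identity <- if (alignedAa) sum(aq[both] == ar[both]) / alignedAa else 0
  list(pass = identity >= cfg$identityMin && alignedAa >= cfg$minAlignedAa,
       identity = identity, alignedAa = alignedAa, status = "ok")
}
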