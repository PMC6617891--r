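## Global pairwise alignment with affine gaps, plus the coordinate maps
## needed to project reference annotation onto a query.

#' Global pairwise alignment with a reference coordinate map
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (a gap run of length L costs \code{gapOpen + gapExtend * L}).
#' Besides the aligned strings, returns the cut-point map used for
#' boundary projection: for every reference cut point b (0..refLen,
#' 0-based half-open coordinates) the number of query bases consumed
#' before that point.
#'
#' @param query,reference nucleotide sequences (character or DNAString).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; defaults
#'   match +2, mismatch -3, gap open 5, gap extend 2 (penalties given as
#'   positive costs).
#' @return list with \code{score}, \code{alignedQuery},
#'   \code{alignedRef}, \code{cutMap} (integer vector of length
#'   refLen + 1), and \code{refToQuery} (per reference base its 1-based
#'   query position, NA when deleted in the query).
#' @export
pairwiseAlignGlobal <- function(query, reference, match = 2, mismatch = -3,
                                gapOpen = 5, gapExtend = 2) {
  q <- as.character(query); r <- as.character(reference)
  if (nchar(q) == 0L || nchar(r) == 0L) {
    hpStop("hp_alignment_error", "cannot align empty sequences")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(q),
    subject = Biostrings::DNAString(r),
    type = "global", substitutionMatrix = sm,
    gapOpening = gapOpen, gapExtension = gapExtend
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  maps <- alignmentMaps(aq, ar)
  list(score = Biostrings::score(pa), alignedQuery = aq, alignedRef = ar,
       cutMap = maps$cutMap, refToQuery = maps$refToQuery)
}

## Derive coordinate maps from a pair of aligned strings.
alignmentMaps <- function(alignedQuery, alignedRef) {
  qc <- strsplit(alignedQuery, "", fixed = TRUE)[[1]]
  rc <- strsplit(alignedRef, "", fixed = TRUE)[[1]]
  stopifnot(length(qc) == length(rc))
  qgap <- qc == "-"
  rgap <- rc == "-"
  qcum <- cumsum(!qgap)   # query bases consumed through column i
  refLen <- sum(!rgap)
  ## cutMap[b + 1] = query bases consumed before reference cut point b
  cutMap <- integer(refLen + 1L)
  refCols <- which(!rgap)
  cutMap[1L] <- if (length(refCols)) qcum[refCols[1L]] - (!qgap[refCols[1L]]) else 0L
  cutMap[-1L] <- qcum[refCols]
  r2q <- ifelse(qgap[refCols], NA_integer_, qcum[refCols])
  list(cutMap = as.integer(cutMap), refToQuery = as.integer(r2q))
}
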