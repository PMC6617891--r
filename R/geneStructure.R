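## Exon/intron annotation by projection from an annotated reference,
## with canonical GT..AG splice-site snapping, and pseudogene detection.

#' Project exon/intron boundaries from a reference onto a query
#'
#' Each reference segment boundary is mapped through a global pairwise
#' alignment, then intron boundaries are snapped to the nearest position
#' within \code{snapWindow} bp such that the intron begins "GT" and ends
#' "AG". An intron whose projected span falls below \code{minIntronLen}
#' is recorded as lost. Boundaries where no canonical dinucleotide is
#' found within the window are kept at the projected position and
#' flagged non-canonical (a warning, not an error).
#'
#' @param query query sequence (character or DNAString), unaligned.
#' @param ref a \linkS4class{ReferenceModel}.
#' @param snapWindow maximum snap distance in bp (default 6).
#' @param minIntronLen spans below this are treated as lost introns
#'   (default 20 bp).
#' @param seqId id recorded in the returned model (default: name of
#'   query, else "query").
#' @param ... scoring parameters passed to \code{pairwiseAlignGlobal}.
#' @return a \linkS4class{GeneModel} for the query.
#' @export
projectExonBoundaries <- function(query, ref, snapWindow = 6L,
                                  minIntronLen = 20L, seqId = NULL, ...) {
  stopifnot(is(ref, "ReferenceModel"))
  q <- as.character(query)
  if (is.null(seqId)) seqId <- names(query) %||% "query"
  aln <- pairwiseAlignGlobal(q, as.character(refSequence(ref)), ...)
  covered <- sum(!is.na(aln$refToQuery)) / length(aln$refToQuery)
  if (covered < 0.5) {
    hpStop("hp_projection_error",
           "query covers only %.0f%% of the reference", 100 * covered)
  }
  seg <- geneSegments(ref)
  qlen <- nchar(q)
  ## project all cut points; enforce monotonicity
  cuts <- aln$cutMap[c(seg$start, seg$end[nrow(seg)]) + 1L]
  cuts <- cummax(cuts)
  cuts[length(cuts)] <- qlen
  cuts[1L] <- 0L
  nseg <- nrow(seg)
  canon5 <- rep(NA, nseg); canon3 <- rep(NA, nseg)
  isIntron <- seg$kind == "intron"
  for (i in which(isIntron)) {
    s <- cuts[i]; e <- cuts[i + 1L]
    if (e - s < minIntronLen) next  # will be flagged lost below
    ## snap 5' boundary to "GT"
    s2 <- snapToMotif(q, s, "GT", snapWindow,
                      lo = if (i > 1L) cuts[i - 1L] else 0L,
                      hi = e - 2L, side = "start")
    ## snap 3' boundary to "AG"
    hiNext <- if (i + 2L <= length(cuts)) cuts[i + 2L] else qlen
    e2 <- snapToMotif(q, e, "AG", snapWindow, lo = (s2 %||% s) + 2L,
                      hi = hiNext, side = "end")
    canon5[i] <- !is.null(s2)
    canon3[i] <- !is.null(e2)
    if (!is.null(s2)) cuts[i] <- s2
    if (!is.null(e2)) cuts[i + 1L] <- e2
  }
  cuts <- cummax(cuts)
  out <- seg
  out$start <- cuts[-length(cuts)]
  out$end <- cuts[-1L]
  out$lost <- isIntron & (out$end - out$start) < minIntronLen
  ## lost introns are collapsed to zero length at their start cut so the
  ## residual bases (if any) stay exonic and the reading frame is judged
  ## on what is actually retained
  for (i in which(out$lost)) {
    resid <- out$end[i] - out$start[i]
    if (resid > 0L && i < nrow(out)) {
      out$end[i] <- out$start[i]
      ## give residual bases to the downstream segment
      out$start[i + 1L] <- out$start[i]
    }
  }
  out$canon5 <- ifelse(out$lost, NA, canon5)
  out$canon3 <- ifelse(out$lost, NA, canon3)
  nc <- which(isIntron & !out$lost & (!canon5 | !canon3))
  if (length(nc)) {
    hpWarn("hp_noncanonical_warning",
           "non-canonical splice site(s) at intron(s) %s of %s",
           paste(seg$index[nc], collapse = ","), seqId)
  }
  geneModel(seqId = seqId, seqLength = qlen, segments = out,
            frameOffset = frameOffset(refModel(ref)))
}

## Find the in-window offset position making substr(q, pos+1, pos+2) == motif
## for side = "start" (GT at intron start) or substr(q, pos-1, pos) == motif
## for side = "end" (AG before intron end cut). Returns NULL when no
## candidate exists. Prefers the smallest |offset| (ties: upstream).
snapToMotif <- function(q, pos, motif, window, lo, hi, side) {
  offs <- order(abs(seq(-window, window)), seq(-window, window))
  cand <- seq(-window, window)[offs]
  for (d in cand) {
    p <- pos + d
    if (p < lo || p > hi) next
    piece <- if (side == "start") substr(q, p + 1L, p + 2L)
             else substr(q, p - 1L, p)
    if (piece == motif) return(as.integer(p))
  }
  NULL
}

#' Intron lengths of a GeneModel
#'
#' @param model a \linkS4class{GeneModel}.
#' @return named integer vector, names = intron indices; lost introns
#'   report 0.
#' @export
intronLengths <- function(model) {
  seg <- geneSegments(model)
  il <- seg[seg$kind == "intron", , drop = FALSE]
  len <- ifelse(il$lost, 0L, il$end - il$start)
  stats::setNames(as.integer(len), as.character(il$index))
}

#' Exon lengths of a GeneModel
#'
#' @param model a \linkS4class{GeneModel}.
#' @return named integer vector, names = exon indices.
#' @export
exonLengths <- function(model) {
  seg <- geneSegments(model)
  el <- seg[seg$kind == "exon", , drop = FALSE]
  stats::setNames(as.integer(el$end - el$start), as.character(el$index))
}

## Concatenated exonic sequence of a model applied to its sequence.
exonicSequence <- function(sequence, model) {
  sq <- as.character(sequence)
  seg <- geneSegments(model)
  ex <- seg[seg$kind == "exon", , drop = FALSE]
  paste(substring(sq, ex$start + 1L, ex$end), collapse = "")
}

#' Detect pseudogenes by frameshift and internal stop codons
#'
#' The exonic segments are concatenated and translated in the frame
#' given by the model's frame offset (standard genetic code; codons
#' containing IUPAC ambiguity translate to 'X' and never count as
#' stops). Frameshift is TRUE iff the exonic length differs from the
#' reference exonic length by a non-multiple of 3.
#'
#' @param query the query sequence (character or DNAString).
#' @param model the query's \linkS4class{GeneModel}.
#' @param ref the \linkS4class{ReferenceModel}.
#' @return a \linkS4class{PseudogeneReport}.
#' @export
detectPseudogene <- function(query, model, ref) {
  cds <- exonicSequence(query, model)
  refLens <- exonLengths(refModel(ref))
  qLens <- exonLengths(model)
  common <- intersect(names(refLens), names(qLens))
  deltas <- qLens[common] - refLens[common]
  exonicIndels <- data.frame(
    exonIndex = as.integer(common[deltas != 0L]),
    delta = as.integer(deltas[deltas != 0L])
  )
  frameshift <- (sum(qLens) - sum(refLens)) %% 3L != 0L
  off <- (3L - frameOffset(model)) %% 3L
  coding <- substr(cds, off + 1L, nchar(cds))
  nCodon <- nchar(coding) %/% 3L
  if (nCodon < 1L) {
    return(new("PseudogeneReport", seqId = model@seqId,
               internalStop = NA, stopPositions = integer(),
               frameshift = frameshift, exonicIndels = exonicIndels,
               undetermined = TRUE))
  }
  coding <- substr(coding, 1L, nCodon * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(coding),
                                           if.fuzzy.codon = "X"))
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
  new("PseudogeneReport", seqId = model@seqId,
      internalStop = length(stops) > 0L,
      stopPositions = as.integer(stops),
      frameshift = frameshift,
      exonicIndels = exonicIndels,
      undetermined = FALSE)
}

#' Is a sequence flagged as a putative pseudogene?
#'
#' @param report a \linkS4class{PseudogeneReport}.
#' @return TRUE when the report shows a frameshift or an internal stop.
#' @export
isPseudogene <- function(report) {
  isTRUE(report@frameshift) || isTRUE(report@internalStop)
}

#' Read a reference model from FASTA plus a segment table
#'
#' The segment table is delimited text with columns \code{kind},
#' \code{index}, \code{start}, \code{end} (0-based half-open) and an
#' optional \code{frame_offset} attribute row is not supported: pass
#' \code{frameOffset} explicitly.
#'
#' @param fastaPath single-record FASTA with the reference sequence.
#' @param segmentsPath delimited table of segments.
#' @param frameOffset codon phase of the first exonic base.
#' @return a \linkS4class{ReferenceModel}.
#' @export
readReferenceModel <- function(fastaPath, segmentsPath, frameOffset = 0L) {
  seqs <- readFastaSeqs(fastaPath)
  if (length(seqs) != 1L) {
    hpStop("hp_parse_error", "reference FASTA must contain exactly one record")
  }
  first <- readLines(segmentsPath, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  seg <- utils::read.table(segmentsPath, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  gm <- geneModel(names(seqs), nchar(as.character(seqs[[1]])), seg,
                  frameOffset = frameOffset)
  referenceModel(as.character(seqs[[1]]), gm)
}

#' Export gene models as a GFF3-like delimited table
#'
#' @param models list of \linkS4class{GeneModel}.
#' @param path output path (TSV).
#' @return invisibly, \code{path}.
#' @export
writeGeneModels <- function(models, path) {
  rows <- lapply(models, function(m) {
    seg <- geneSegments(m)
    data.frame(seq_id = m@seqId, kind = seg$kind, index = seg$index,
               start = seg$start, end = seg$end, lost = seg$lost)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
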