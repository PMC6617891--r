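## S4 classes for the central data objects.

#' GeneModel: exon/intron architecture of one sequence
#'
#' An ordered, gap-free tiling of a nucleotide sequence into exon and
#' intron segments, with a reading-frame anchor for the first exonic
#' base. Coordinates are 0-based, half-open throughout the package.
#' Intron segments may have zero (or near-zero) length only when they
#' are flagged as lost.
#'
#' @slot seqId character(1), identifier of the annotated sequence.
#' @slot seqLength integer(1), length of the sequence in bp.
#' @slot segments data.frame with columns \code{kind} ("exon"/"intron"),
#'   \code{index} (segment index within the gene), \code{start},
#'   \code{end} (0-based half-open), \code{lost} (logical, introns only),
#'   \code{canon5}, \code{canon3} (logical; GT / AG splice dinucleotide
#'   found; NA for exons and lost introns).
#' @slot frameOffset integer(1) in 0..2, codon phase of the first
#'   exonic base (0 = the first exonic base starts a codon).
#' @export
setClass("GeneModel",
  representation(
    seqId = "character",
    seqLength = "integer",
    segments = "data.frame",
    frameOffset = "integer"
  )
)

setValidity("GeneModel", function(object) {
  seg <- object@segments
  msgs <- character()
  need <- c("kind", "index", "start", "end", "lost", "canon5", "canon3")
  if (!all(need %in% names(seg))) {
    return(sprintf("segments must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(seg) == 0L) return("segments must be non-empty")
  if (!all(seg$kind %in% c("exon", "intron"))) msgs <- c(msgs, "kind must be exon or intron")
  if (seg$start[1L] != 0L) msgs <- c(msgs, "first segment must start at 0")
  if (seg$end[nrow(seg)] != object@seqLength) {
    msgs <- c(msgs, "last segment must end at sequence length")
  }
  if (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)])) {
    msgs <- c(msgs, "segments must tile the sequence without gaps or overlaps")
  }
  if (any(seg$end < seg$start)) msgs <- c(msgs, "segment end < start")
  if (nrow(seg) > 1L && any(seg$kind[-1L] == seg$kind[-nrow(seg)])) {
    msgs <- c(msgs, "segment kinds must alternate exon/intron")
  }
  for (k in c("exon", "intron")) {
    idx <- seg$index[seg$kind == k]
    if (length(idx) > 1L && any(diff(idx) <= 0L)) {
      msgs <- c(msgs, sprintf("%s indices must be strictly increasing", k))
    }
  }
  zero <- seg$kind == "intron" & (seg$end - seg$start) == 0L & !seg$lost
  if (any(zero)) msgs <- c(msgs, "zero-length introns must be flagged lost")
  if (!(object@frameOffset %in% 0:2)) msgs <- c(msgs, "frameOffset must be in 0..2")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GeneModel
#'
#' @param seqId sequence identifier.
#' @param seqLength sequence length in bp.
#' @param segments data.frame with at least \code{kind}, \code{index},
#'   \code{start}, \code{end}; \code{lost}, \code{canon5}, \code{canon3}
#'   are filled with defaults if absent.
#' @param frameOffset codon phase (0..2) of the first exonic base.
#' @return a validated \linkS4class{GeneModel}.
#' @export
geneModel <- function(seqId, seqLength, segments, frameOffset = 0L) {
  if (is.null(segments$lost)) segments$lost <- FALSE
  if (is.null(segments$canon5)) segments$canon5 <- NA
  if (is.null(segments$canon3)) segments$canon3 <- NA
  segments$lost[segments$kind == "exon"] <- FALSE
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$index <- as.integer(segments$index)
  new("GeneModel",
    seqId = as.character(seqId),
    seqLength = as.integer(seqLength),
    segments = segments,
    frameOffset = as.integer(frameOffset)
  )
}

#' ReferenceModel: annotation source sequence plus its GeneModel
#'
#' The reference amplicon with trusted exon/intron annotation; every
#' non-lost intron must carry canonical GT...AG splice dinucleotides.
#'
#' @slot sequence a \link[Biostrings]{DNAString}.
#' @slot model the \linkS4class{GeneModel} annotating \code{sequence}.
#' @export
setClass("ReferenceModel",
  representation(sequence = "DNAString", model = "GeneModel")
)

setValidity("ReferenceModel", function(object) {
  if (length(object@sequence) != object@model@seqLength) {
    return("model seqLength does not match sequence length")
  }
  seg <- object@model@segments
  sq <- as.character(object@sequence)
  bad <- character()
  for (i in which(seg$kind == "intron" & !seg$lost)) {
    s <- seg$start[i]; e <- seg$end[i]
    if (substr(sq, s + 1L, s + 2L) != "GT" || substr(sq, e - 1L, e) != "AG") {
      bad <- c(bad, as.character(seg$index[i]))
    }
  }
  if (length(bad)) {
    sprintf("reference introns must begin GT and end AG (violated: %s)",
            paste(bad, collapse = ","))
  } else TRUE
})

#' Construct a ReferenceModel
#'
#' @param sequence DNAString (or character) reference sequence.
#' @param model \linkS4class{GeneModel} for the sequence.
#' @return a validated \linkS4class{ReferenceModel}.
#' @export
referenceModel <- function(sequence, model) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("ReferenceModel", sequence = sequence, model = model)
}

#' PseudogeneReport: frameshift and stop-codon diagnostics
#'
#' @slot seqId character(1).
#' @slot internalStop logical(1): any stop codon in the translated
#'   exonic concatenation (all stops in this gene-internal amplicon are
#'   internal).
#' @slot stopPositions integer, 1-based codon indices of stop codons.
#' @slot frameshift logical(1): total exonic length differs from the
#'   reference by a non-multiple of 3.
#' @slot exonicIndels data.frame (exonIndex, delta) of per-exon length
#'   differences vs the reference.
#' @slot undetermined logical(1): exonic region shorter than one codon.
#' @export
setClass("PseudogeneReport",
  representation(
    seqId = "character",
    internalStop = "logical",
    stopPositions = "integer",
    frameshift = "logical",
    exonicIndels = "data.frame",
    undetermined = "logical"
  )
)

setValidity("PseudogeneReport", function(object) {
  if (isTRUE(object@internalStop) && length(object@stopPositions) == 0L) {
    "internalStop implies non-empty stopPositions"
  } else TRUE
})

#' OriginCall: allo/auto verdict for one individual
#'
#' @slot individualId character(1).
#' @slot verdict one of "ALLOPOLYPLOID_PATTERN", "AUTOPOLYPLOID_PATTERN",
#'   "UNINFORMATIVE".
#' @slot patternLabel display label; equals the verdict except that an
#'   allopolyploid-style pattern in a diploid is reported as
#'   "hybrid-pattern".
#' @slot copies data.frame (seqId, label, clade, cladeSupport).
#' @slot minSeparatingSupport numeric(1), minimum bootstrap support of
#'   the clades separating the copies (NA when not applicable).
#' @slot rationale character(1), human-readable justification.
#' @export
setClass("OriginCall",
  representation(
    individualId = "character",
    verdict = "character",
    patternLabel = "character",
    copies = "data.frame",
    minSeparatingSupport = "numeric",
    rationale = "character"
  )
)

setValidity("OriginCall", function(object) {
  ok <- c("ALLOPOLYPLOID_PATTERN", "AUTOPOLYPLOID_PATTERN", "UNINFORMATIVE")
  msgs <- character()
  if (!(object@verdict %in% ok)) msgs <- c(msgs, "unknown verdict")
  if (object@verdict == "ALLOPOLYPLOID_PATTERN") {
    cl <- unique(object@copies$clade[!is.na(object@copies$clade) &
                                       object@copies$clade != "unassigned"])
    if (nrow(object@copies) < 2L || length(cl) < 2L) {
      msgs <- c(msgs, "allopolyploid pattern requires >= 2 copies in >= 2 clades")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneModel", function(object) {
  seg <- object@segments
  nI <- sum(seg$kind == "intron")
  cat(sprintf("GeneModel for '%s' (%d bp): %d exon / %d intron segments, frame offset %d\n",
              object@seqId, object@seqLength, sum(seg$kind == "exon"), nI,
              object@frameOffset))
  il <- seg[seg$kind == "intron", ]
  if (nrow(il)) {
    cat("  introns: ",
        paste(sprintf("%d:%dbp%s", il$index, il$end - il$start,
                      ifelse(il$lost, " (lost)", "")), collapse = ", "),
        "\n", sep = "")
  }
})

setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf("ReferenceModel (%d bp)\n", length(object@sequence)))
  show(object@model)
})

setMethod("show", "PseudogeneReport", function(object) {
  cat(sprintf("PseudogeneReport '%s': internalStop=%s frameshift=%s%s\n",
              object@seqId, object@internalStop, object@frameshift,
              if (object@undetermined) " (undetermined)" else ""))
  if (length(object@stopPositions)) {
    cat("  stop codons at:", paste(object@stopPositions, collapse = ", "), "\n")
  }
})

setMethod("show", "OriginCall", function(object) {
  cat(sprintf("OriginCall '%s': %s (%s)\n", object@individualId,
              object@verdict, object@patternLabel))
  cat(sprintf("  %d copies; min separating support: %s\n",
              nrow(object@copies),
              ifelse(is.na(object@minSeparatingSupport), "NA",
                     format(object@minSeparatingSupport))))
  cat("  ", object@rationale, "\n", sep = "")
})

## ---- accessors ----------------------------------------------------------

#' @rdname geneModel
#' @param object,x a GeneModel / ReferenceModel.
#' @export
setGeneric("geneSegments", function(object) standardGeneric("geneSegments"))

#' @rdname geneModel
#' @export
setMethod("geneSegments", "GeneModel", function(object) object@segments)

#' @rdname geneModel
#' @export
setMethod("geneSegments", "ReferenceModel", function(object) object@model@segments)

#' @rdname geneModel
#' @export
setGeneric("frameOffset", function(object) standardGeneric("frameOffset"))

#' @rdname geneModel
#' @export
setMethod("frameOffset", "GeneModel", function(object) object@frameOffset)

#' @rdname referenceModel
#' @param object a ReferenceModel.
#' @export
setGeneric("refSequence", function(object) standardGeneric("refSequence"))

#' @rdname referenceModel
#' @export
setMethod("refSequence", "ReferenceModel", function(object) object@sequence)

#' @rdname referenceModel
#' @export
setGeneric("refModel", function(object) standardGeneric("refModel"))

#' @rdname referenceModel
#' @export
setMethod("refModel", "ReferenceModel", function(object) object@model)

#' @rdname classifyOrigin
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname classifyOrigin
#' @export
setMethod("verdict", "OriginCall", function(object) object@verdict)
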