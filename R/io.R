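## Readers/writers for FASTA, Newick and the sample metadata table.

#' Read nucleotide sequences from FASTA
#'
#' Residues are upper-cased and 'U' is mapped to 'T'. With
#' \code{aligned = TRUE} all sequences must have equal length
#' (gap characters '-' and missing '?' are permitted).
#'
#' @param path path to a FASTA file.
#' @param aligned logical; require equal-length (aligned) sequences.
#' @return a named \link[Biostrings]{DNAStringSet}; names are the first
#'   whitespace-delimited token of each header, the remainder is kept in
#'   the \code{description} attribute (a character vector parallel to
#'   the set).
#' @export
readFastaSeqs <- function(path, aligned = FALSE) {
  if (!file.exists(path)) hpStop("hp_parse_error", "file not found: %s", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) hpStop("hp_parse_error", "FASTA parse failure in %s: %s",
                               path, conditionMessage(e))
  )
  if (length(raw) == 0L) hpStop("hp_parse_error", "empty FASTA file: %s", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- normalizeResidues(as.character(raw))
  if (any(nchar(res) == 0L)) {
    hpStop("hp_parse_error", "empty sequence record in %s", path)
  }
  bad <- grepl(sprintf("[^%s?-]", paste(IUPAC_NT, collapse = "")), res)
  if (any(bad)) {
    hpStop("hp_parse_error", "non-IUPAC characters in record(s): %s",
           paste(ids[bad], collapse = ", "))
  }
  if (aligned && length(unique(nchar(res))) != 1L) {
    hpStop("hp_alignment_error",
           "aligned=TRUE but sequence lengths differ (%s)",
           paste(range(nchar(res)), collapse = "-"))
  }
  ## '?' (missing) is normalized to 'N': both are treated as missing data
  ## by every downstream statistic, and 'N' is in the DNAStringSet alphabet.
  out <- Biostrings::DNAStringSet(gsub("?", "N", res, fixed = TRUE))
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x a named DNAStringSet or named character vector.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastaSeqs <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read the sample metadata table
#'
#' One row per individual; comma or tab delimited (auto-detected).
#' Required columns: \code{individual_id}, \code{taxon_name},
#' \code{section}, \code{subsection}, \code{ploidy}, \code{accessions}
#' (semicolon-separated sequence ids, may be empty). Unknown ploidy may
#' be written as "NA", "" or "unknown" and is returned as NA.
#'
#' @param path path to the delimited table.
#' @return data.frame with one row per individual; \code{ploidy} is
#'   integer (NA = unknown).
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) hpStop("hp_parse_error", "file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", colClasses = "character")
  required <- c("individual_id", "taxon_name", "section", "subsection",
                "ploidy", "accessions")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    hpStop("hp_schema_error", "metadata missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup)) {
    hpStop("hp_validation_error", "duplicate individual_id: %s",
           paste(unique(dup), collapse = ", "))
  }
  pl <- trimws(df$ploidy)
  unknown <- is.na(pl) | pl %in% c("", "NA", "na", "unknown", "?")
  plN <- suppressWarnings(as.integer(pl))
  if (any(!unknown & is.na(plN))) {
    hpStop("hp_validation_error", "unparseable ploidy value(s): %s",
           paste(unique(pl[!unknown & is.na(plN)]), collapse = ", "))
  }
  if (any(!unknown & plN < 2L)) {
    hpStop("hp_validation_error", "ploidy must be >= 2 when known")
  }
  df$ploidy <- ifelse(unknown, NA_integer_, plN)
  df
}

#' Write the sample metadata table
#'
#' @param meta data.frame as returned by \code{readSampleMetadata}.
#' @param path output path.
#' @param sep field separator ("," or "\t").
#' @return invisibly, \code{path}.
#' @export
writeSampleMetadata <- function(meta, path, sep = ",") {
  out <- meta
  out$ploidy <- ifelse(is.na(out$ploidy), "NA", as.character(out$ploidy))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split the accessions field of a metadata table
#'
#' @param meta metadata data.frame.
#' @return named list individual_id -> character vector of accessions.
#' @export
accessionsOf <- function(meta) {
  out <- lapply(meta$accessions, function(a) {
    if (is.null(a) || is.na(a)) a <- ""
    a <- trimws(strsplit(a, ";", fixed = TRUE)[[1]])
    a[nzchar(a)]
  })
  stats::setNames(out, meta$individual_id)
}

#' Map sequence ids to individuals
#'
#' A sequence id resolves to an individual either through the metadata
#' \code{accessions} field or, failing that, by the convention that the
#' id is \code{<individual_id><sep><copy>}. Every sequence must resolve
#' to exactly one individual.
#'
#' @param seqIds character vector of sequence ids.
#' @param meta metadata data.frame.
#' @param sep separator for the prefix convention (default "__").
#' @return named character vector seq_id -> individual_id.
#' @export
mapSequencesToIndividuals <- function(seqIds, meta, sep = "__") {
  acc <- accessionsOf(meta)
  lookup <- stats::setNames(
    rep(names(acc), lengths(acc)),
    unlist(acc, use.names = FALSE)
  )
  if (any(duplicated(names(lookup)))) {
    hpStop("hp_validation_error", "accession listed for multiple individuals: %s",
           paste(unique(names(lookup)[duplicated(names(lookup))]), collapse = ", "))
  }
  ind <- unname(lookup[seqIds])
  pref <- sub(paste0(sep, ".*$"), "", seqIds)
  ind[is.na(ind)] <- ifelse(pref[is.na(ind)] %in% meta$individual_id,
                            pref[is.na(ind)], NA_character_)
  if (anyNA(ind)) {
    hpStop("hp_join_error", "sequence(s) with no matching individual: %s",
           paste(seqIds[is.na(ind)], collapse = ", "))
  }
  stats::setNames(ind, seqIds)
}

#' Read a Newick tree
#'
#' Internal-node labels are interpreted as bootstrap supports in
#' [0, 100] when numeric. Duplicate leaf labels are rejected.
#'
#' @param path path to a Newick file.
#' @return an \link[ape]{ape} \code{phylo} object.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) hpStop("hp_parse_error", "file not found: %s", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    hpStop("hp_parse_error", "Newick parse failure in %s", path)
  }
  if (any(duplicated(tr$tip.label))) {
    hpStop("hp_validation_error", "duplicate leaf label(s): %s",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    num <- !is.na(sup)
    if (any(num & (sup < 0 | sup > 100))) {
      hpStop("hp_validation_error", "support values must lie in [0, 100]")
    }
  }
  tr
}

#' Write a Newick tree
#'
#' @param tree a \code{phylo} object (supports, if any, in
#'   \code{node.label}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
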