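#' Read tandem repeat alleles from FASTA
#'
#' Reads a multi-record FASTA (wrapped or unwrapped lines). Record ids are
#' the first whitespace-delimited token of each header and must be unique;
#' sequences are upper-cased and validated as ACGTN.
#'
#' @param path FASTA file path.
#' @return Named character vector of allele sequences, file order preserved.
#' @export
read_alleles <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("FASTA file contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  stats::setNames(unname(seqs), ids)
}

#' Read motifs from a one-per-line text file
#'
#' Blank lines and `#` comment lines are ignored; motifs are upper-cased and
#' validated as ACGT.
#'
#' @param path File path.
#' @return Character vector of motifs.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("motif file contains no motifs", call. = FALSE)
  .check_motifs(lines)
}

#' Read a sample annotation table
#'
#' TSV with a required header containing columns `sample` and `group`.
#'
#' @param path File path.
#' @return Named character vector: group label per sample.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "group") %in% names(tab))) {
    stop("annotation TSV must have header columns 'sample' and 'group'",
         call. = FALSE)
  }
  if (anyDuplicated(tab$sample)) {
    stop("duplicate samples in annotation TSV", call. = FALSE)
  }
  stats::setNames(as.character(tab$group), tab$sample)
}

#' Write decompositions as a segment TSV
#'
#' One row per segment with columns `allele_id`, `segment_index` (0-based),
#' `substring`, `aligned_motif`, `origin`, `segment_score`.
#'
#' @param decompositions A `tr_decomposition_set` (or list of
#'   `tr_decomposition`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_decomposition_tsv <- function(decompositions, path) {
  if (inherits(decompositions, "tr_decomposition_set")) {
    decompositions <- decompositions$decompositions
  }
  rows <- do.call(rbind, lapply(decompositions, function(d) {
    cbind(allele_id = d$allele_id,
          d$segments[, c("segment_index", "substring", "aligned_motif",
                         "origin", "segment_score")])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an encoded alignment as FASTA over the symbol alphabet
#'
#' Gap-padded rows (gap character `-`) are written as FASTA records in the
#' given order for interchange with other tools.
#'
#' @param a An `encoded_alignment`.
#' @param path File path.
#' @param order Optional `row_order`.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(a, path, order = NULL) {
  stopifnot(inherits(a, "encoded_alignment"))
  rows <- a$rows
  if (!is.null(order)) rows <- rows[order$order]
  set <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
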