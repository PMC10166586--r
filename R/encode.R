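#' The 90-character symbol alphabet
#'
#' Ordered alphabet used to encode motifs as single characters: digits
#' (1-9 then 0), upper-case letters, lower-case letters, then 28 punctuation
#' characters in ASCII order. The gap character `-`, the private-motif symbol
#' `?`, whitespace, and the quoting hazards `"` and `\` are excluded.
#'
#' @return Character vector of exactly 90 single characters.
#' @export
symbol_alphabet <- function() {
  punct <- c("!", "#", "$", "%", "&", "'", "(", ")", "*", "+", ",", ".",
             "/", ":", ";", "<", "=", ">", "@", "[", "]", "^", "_", "`",
             "{", "|", "}", "~")
  c(as.character(c(1:9, 0)), LETTERS, letters, punct)
}

#' Reserved symbols
#'
#' `private_symbol()` is the single character (`?`) shared by all motifs whose
#' frequency falls below the private threshold; `gap_symbol()` is the
#' alignment gap character (`-`). Neither can be assigned to a motif.
#' @return A single character.
#' @export
private_symbol <- function() "?"

#' @rdname private_symbol
#' @export
gap_symbol <- function() "-"

# Count motif occurrences per segment across a decomposition set / list.
.segment_motif_counts <- function(decompositions) {
  if (inherits(decompositions, "tr_decomposition_set")) {
    decompositions <- decompositions$decompositions
  }
  if (inherits(decompositions, "tr_decomposition")) {
    decompositions <- list(decompositions)
  }
  if (!length(decompositions)) {
    stop("`decompositions` must be non-empty", call. = FALSE)
  }
  motifs <- unlist(lapply(decompositions, function(d) d$segments$substring),
                   use.names = FALSE)
  tab <- table(motifs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the motif-to-symbol mapping
#'
#' Maps every distinct motif observed across the decompositions (counting one
#' occurrence per segment) to a single-character symbol from
#' [symbol_alphabet()]. Motifs whose count falls below `threshold` are
#' collapsed into the private class and share [private_symbol()]. Symbols are
#' assigned in descending count order (ties broken by lexicographic motif
#' order), so symbol rank mirrors motif frequency. At most 90 motifs may
#' receive their own symbol; `threshold = "auto"` picks the smallest
#' threshold t >= 1 for which at most 90 motifs reach it, maximizing the
#' number of distinct symbols.
#'
#' @param decompositions A `tr_decomposition_set`, a single
#'   `tr_decomposition`, or a list of them.
#' @param threshold Positive integer count, or `"auto"`.
#' @return An object of class `motif_mapping`: list with `entries`
#'   (data.frame `symbol`, `motif`, `count`), `private` (data.frame `motif`,
#'   `count`), `private_symbol` and `threshold` (the effective threshold).
#' @examples
#' d <- decompose_alleles(c(a = "ACCTTGACCTTGACCTTTG"), "ACCTTG")
#' motif_mapping(d, threshold = 1)
#' @export
motif_mapping <- function(decompositions, threshold = "auto") {
  counts <- .segment_motif_counts(decompositions)
  # order: descending count, ties lexicographic (byte order, locale-free)
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]

  if (identical(threshold, "auto")) {
    t_eff <- 1L
    while (sum(counts >= t_eff) > 90L) t_eff <- t_eff + 1L
  } else {
    t_eff <- as.integer(threshold)
    if (is.na(t_eff) || t_eff < 1L) {
      stop("`threshold` must be a positive integer or \"auto\"", call. = FALSE)
    }
    if (sum(counts >= t_eff) > 90L) {
      stop(sprintf(paste0("%d motifs reach the frequency threshold %d but only ",
                          "90 symbols are available; raise `threshold` or use ",
                          "threshold = \"auto\""),
                   sum(counts >= t_eff), t_eff), call. = FALSE)
    }
  }

  keep <- counts >= t_eff
  entries <- data.frame(
    symbol = symbol_alphabet()[seq_len(sum(keep))],
    motif = names(counts)[keep],
    count = unname(counts[keep]),
    stringsAsFactors = FALSE
  )
  private <- data.frame(
    motif = names(counts)[!keep],
    count = unname(counts[!keep]),
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries, private = private,
                 private_symbol = private_symbol(), threshold = t_eff),
            class = "motif_mapping")
}

# symbol lookup table: motif -> symbol (private motifs -> private symbol)
.mapping_lookup <- function(mapping) {
  stats::setNames(
    c(mapping$entries$symbol, rep(mapping$private_symbol, nrow(mapping$private))),
    c(mapping$entries$motif, mapping$private$motif)
  )
}

#' Encode a decomposed allele as a symbol string
#'
#' Substitutes each segment's motif with its mapped symbol; segment i of the
#' decomposition becomes character i of the output.
#'
#' @param d A `tr_decomposition`.
#' @param mapping A [motif_mapping()].
#' @return A single character string, one symbol per segment.
#' @export
encode_allele <- function(d, mapping) {
  stopifnot(inherits(d, "tr_decomposition"), inherits(mapping, "motif_mapping"))
  motifs <- d$segments$substring
  if (!length(motifs)) return("")
  lut <- .mapping_lookup(mapping)
  missing <- setdiff(motifs, names(lut))
  if (length(missing)) {
    stop("motif(s) absent from mapping: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  paste(lut[motifs], collapse = "")
}

#' Encode every allele of a decomposition set
#'
#' @param decompositions A `tr_decomposition_set` (or list of
#'   `tr_decomposition`).
#' @param mapping A [motif_mapping()].
#' @return Named character vector of encoded alleles, input order preserved.
#' @export
encode_alleles <- function(decompositions, mapping) {
  if (inherits(decompositions, "tr_decomposition_set")) {
    decompositions <- decompositions$decompositions
  }
  vapply(decompositions, encode_allele, "", mapping = mapping)
}

#' Write / read a motif mapping as TSV
#'
#' The file has a header comment line carrying the private threshold, then a
#' `symbol  motif  count` header and one row per motif; private motifs all
#' carry the reserved private symbol. `read_mapping(write_mapping(m))`
#' reproduces `m` exactly.
#'
#' @param mapping A [motif_mapping()].
#' @param path File path.
#' @return `write_mapping` returns `path` invisibly; `read_mapping` returns a
#'   `motif_mapping`.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "motif_mapping"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#private_threshold\t%d", mapping$threshold), con)
  writeLines("symbol\tmotif\tcount", con)
  rows <- rbind(
    mapping$entries,
    if (nrow(mapping$private))
      data.frame(symbol = mapping$private_symbol, motif = mapping$private$motif,
                 count = mapping$private$count, stringsAsFactors = FALSE)
  )
  if (!is.null(rows) && nrow(rows)) {
    writeLines(sprintf("%s\t%s\t%d", rows$symbol, rows$motif, rows$count), con)
  }
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#private_threshold\t")) {
    stop("line 1: expected '#private_threshold\t<int>' header", call. = FALSE)
  }
  t_eff <- suppressWarnings(as.integer(sub("^#private_threshold\t", "", lines[1L])))
  if (is.na(t_eff)) stop("line 1: malformed threshold", call. = FALSE)
  if (!identical(lines[2L], "symbol\tmotif\tcount")) {
    stop("line 2: expected header 'symbol\tmotif\tcount'", call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  sym <- chr <- character(length(body)); cnt <- integer(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L || !nzchar(f[1]) || !nzchar(f[2])) {
      stop(sprintf("line %d: expected 3 tab-separated fields", i + 2L), call. = FALSE)
    }
    cnt[i] <- suppressWarnings(as.integer(f[3]))
    if (is.na(cnt[i])) stop(sprintf("line %d: malformed count '%s'", i + 2L, f[3]),
                            call. = FALSE)
    sym[i] <- f[1]; chr[i] <- f[2]
  }
  is_priv <- sym == private_symbol()
  if (anyDuplicated(sym[!is_priv])) {
    dup <- sym[!is_priv][duplicated(sym[!is_priv])][1L]
    line <- which(!is_priv & sym == dup)[2L] + 2L
    stop(sprintf("line %d: duplicate symbol '%s'", line, dup), call. = FALSE)
  }
  if (anyDuplicated(chr)) {
    line <- which(duplicated(chr))[1L] + 2L
    stop(sprintf("line %d: duplicate motif '%s'", line, chr[duplicated(chr)][1L]),
         call. = FALSE)
  }
  structure(list(
    entries = data.frame(symbol = sym[!is_priv], motif = chr[!is_priv],
                         count = cnt[!is_priv], stringsAsFactors = FALSE),
    private = data.frame(motif = chr[is_priv], count = cnt[is_priv],
                         stringsAsFactors = FALSE),
    private_symbol = private_symbol(), threshold = t_eff
  ), class = "motif_mapping")
}

#' @export
print.motif_mapping <- function(x, ...) {
  cat(sprintf("Motif mapping: %d symbols, %d private motifs (threshold %d)\n",
              nrow(x$entries), nrow(x$private), x$threshold))
  if (nrow(x$entries)) {
    show <- utils::head(x$entries, 10L)
    cat(sprintf("  %s = %s (%d)\n", show$symbol, show$motif, show$count), sep = "")
    if (nrow(x$entries) > 10L) cat(sprintf("  ... %d more\n", nrow(x$entries) - 10L))
  }
  invisible(x)
}
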