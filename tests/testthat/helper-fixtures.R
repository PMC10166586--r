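# shared test helpers: random instances and independent alignment oracles

BASES <- c("A", "C", "G", "T")

all_4mers <- apply(expand.grid(BASES, BASES, BASES, BASES), 1, paste,
                   collapse = "")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_motif_set <- function(max_motifs = 3, max_len = 5) {
  k <- sample(seq_len(max_motifs), 1)
  unique(replicate(k, random_dna(sample(seq_len(max_len), 1))))
}

# a synthetic decomposition carrying the given segment substrings; enough
# structure for the encoding module, which only reads segments$substring
fake_decomposition <- function(substrings, id = "a") {
  structure(list(
    allele_id = id,
    segments = data.frame(
      segment_index = seq_along(substrings) - 1L,
      substring = substrings,
      aligned_motif = substrings,
      segment_score = 5 * nchar(substrings),
      is_exact = TRUE,
      origin = "input",
      stringsAsFactors = FALSE
    ),
    total_score = sum(5 * nchar(substrings)),
    input_motifs = unique(substrings)
  ), class = "tr_decomposition")
}

fake_alignment <- function(rows) {
  structure(list(rows = rows, width = nchar(rows[[1]]), score = NA_real_),
            class = "encoded_alignment")
}

# plain-loop affine-gap global alignment over symbol vectors: the pairwise
# oracle for the MSA (independent of the package's vectorised Gotoh)
oracle_pairwise_score <- function(a, b, M, go, ge) {
  na <- length(a); nb <- length(b)
  NEG <- -1e15
  mm <- matrix(NEG, na + 1, nb + 1)
  gx <- matrix(NEG, na + 1, nb + 1)  # gap in b
  gy <- matrix(NEG, na + 1, nb + 1)  # gap in a
  mm[1, 1] <- 0
  for (i in seq_len(na)) gx[i + 1, 1] <- go + ge * (i - 1)
  for (j in seq_len(nb)) gy[1, j + 1] <- go + ge * (j - 1)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      s <- M[a[i], b[j]]
      mm[i + 1, j + 1] <- s + max(mm[i, j], gx[i, j], gy[i, j])
      gx[i + 1, j + 1] <- max(mm[i, j + 1] + go, gy[i, j + 1] + go,
                              gx[i, j + 1] + ge)
      gy[i + 1, j + 1] <- max(mm[i + 1, j] + go, gx[i + 1, j] + go,
                              gy[i + 1, j] + ge)
    }
  }
  max(mm[na + 1, nb + 1], gx[na + 1, nb + 1], gy[na + 1, nb + 1])
}

# a motif mapping over k symbols with distinct random motifs (for alignment
# tests that need an arbitrary symbol universe)
mapping_of_motifs <- function(motifs) {
  motif_mapping(fake_decomposition(motifs), threshold = 1)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

write_fasta_text <- function(records, path, wrap = NULL) {
  lines <- unlist(lapply(names(records), function(id) {
    seq <- records[[id]]
    body <- if (is.null(wrap)) seq else {
      starts <- seq(1, nchar(seq), by = wrap)
      substring(seq, starts, pmin(starts + wrap - 1, nchar(seq)))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
}
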