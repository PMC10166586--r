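#' Simulate synthetic tandem repeat alleles
#'
#' Generates alleles as concatenations of mutated motif copies, with a truth
#' table recording the generating motif of every copy. Each copy is drawn
#' uniformly from `motifs`, then mutated independently: every base is
#' substituted with probability `sub_rate` (to a uniformly chosen different
#' base) and, independently, every base suffers a length-1 indel with
#' probability `indel_rate` (deletion or insertion of a uniform base after
#' it, with equal probability). Deterministic for a fixed `seed`.
#'
#' @param motifs Character vector of ACGT motifs to repeat.
#' @param n_alleles Number of alleles to simulate.
#' @param copy_range Integer vector `c(min, max)`: copies per allele are
#'   drawn uniformly from this range.
#' @param sub_rate Per-base substitution probability in `[0, 1]`.
#' @param indel_rate Per-base single-base indel probability in `[0, 1]`.
#' @param groups Optional character vector of group labels; each allele is
#'   assigned one uniformly at random.
#' @param seed Optional integer seed.
#' @param fasta,truth_tsv Optional output paths: the alleles as FASTA and
#'   the truth table as TSV (`allele_id`, `copy_index` 0-based,
#'   `true_motif`).
#' @return A list with `sequences` (named character vector), `truth`
#'   (data.frame `allele_id`, `copy_index`, `true_motif`) and `groups`
#'   (named character vector or `NULL`).
#' @examples
#' sim <- simulate_tr_alleles("ACG", n_alleles = 2, copy_range = c(5, 5),
#'                            seed = 1)
#' sim$sequences
#' @export
simulate_tr_alleles <- function(motifs, n_alleles = 10, copy_range = c(5, 15),
                                sub_rate = 0, indel_rate = 0, groups = NULL,
                                seed = NULL, fasta = NULL, truth_tsv = NULL) {
  motifs <- .check_motifs(motifs)
  if (sub_rate < 0 || sub_rate > 1 || indel_rate < 0 || indel_rate > 1) {
    stop("mutation rates must lie in [0, 1]", call. = FALSE)
  }
  copy_range <- as.integer(copy_range)
  if (length(copy_range) != 2L || any(copy_range < 1L) ||
      copy_range[2L] < copy_range[1L]) {
    stop("`copy_range` must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("allele_%03d", seq_len(n_alleles))
  seqs <- character(n_alleles)
  truth <- vector("list", n_alleles)
  for (i in seq_len(n_alleles)) {
    ncopy <- copy_range[1L] + sample.int(copy_range[2L] - copy_range[1L] + 1L, 1L) - 1L
    src <- sample(motifs, ncopy, replace = TRUE)
    copies <- vapply(src, .mutate_copy, "", sub_rate = sub_rate,
                     indel_rate = indel_rate, bases = bases, USE.NAMES = FALSE)
    seqs[i] <- paste(copies, collapse = "")
    truth[[i]] <- data.frame(allele_id = ids[i],
                             copy_index = seq_len(ncopy) - 1L,
                             true_motif = src, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  grp <- if (!is.null(groups)) {
    stats::setNames(sample(groups, n_alleles, replace = TRUE), ids)
  }
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, ids)), fasta)
  }
  if (!is.null(truth_tsv)) {
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(sequences = stats::setNames(seqs, ids), truth = truth, groups = grp)
}

.mutate_copy <- function(motif, sub_rate, indel_rate, bases) {
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (sub_rate > 0) {
    hit <- stats::runif(length(ch)) < sub_rate
    for (k in which(hit)) ch[k] <- sample(setdiff(bases, ch[k]), 1L)
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (k in seq_along(ch)) {
      if (stats::runif(1L) < indel_rate) {
        if (stats::runif(1L) < 0.5) next            # deletion
        out <- c(out, ch[k], sample(bases, 1L))     # insertion after
      } else {
        out <- c(out, ch[k])
      }
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

#' Brute-force decomposition oracle
#'
#' Independent check of [decompose_tr()] for tiny inputs: enumerates every
#' partition of `x` into consecutive non-empty parts (there are
#' `2^(nchar(x)-1)` of them) by exhaustive recursion, scores each part
#' against its best motif with a plain quadratic global-alignment DP, and
#' returns the maximal total. Intended for validation only.
#'
#' @param x DNA string with at most 20 characters.
#' @param motifs Character vector of motifs.
#' @param params [scoring_params()].
#' @return The optimal total score (a single number).
#' @examples
#' brute_force_decompose("ACG", "ACG")  # 15
#' @export
brute_force_decompose <- function(x, motifs, params = scoring_params()) {
  params <- .check_params(params)
  x <- .check_dna(x, "x", allow_n = TRUE)
  motifs <- .check_motifs(motifs)
  n <- nchar(x)
  if (n > 20L) {
    stop("`x` longer than 20 bases: exhaustive enumeration refused", call. = FALSE)
  }
  # score of every substring against its best motif, by plain textbook NW
  part <- base::matrix(-Inf, n, n)
  for (s in seq_len(n)) {
    for (e in s:n) {
      part[s, e] <- max(vapply(motifs, .oracle_nw, 0,
                               x = substr(x, s, e), params = params))
    }
  }
  best_from <- function(s) {
    if (s > n) return(0)
    max(vapply(s:n, function(e) part[s, e] + best_from(e + 1L), 0))
  }
  best_from(1L)
}

# deliberately plain O(|a||b|) global alignment, independent of the
# vectorised implementation in scoring.R
.oracle_nw <- function(m, x, params) {
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- strsplit(m, "", fixed = TRUE)[[1]]
  H <- base::matrix(0, length(a) + 1L, length(b) + 1L)
  for (i in seq_along(a)) H[i + 1L, 1L] <- i * params$indel
  for (j in seq_along(b)) H[1L, j + 1L] <- j * params$indel
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      s <- if (a[i] == b[j] && a[i] != "N") params$match else params$mismatch
      H[i + 1L, j + 1L] <- max(H[i, j] + s,
                               H[i, j + 1L] + params$indel,
                               H[i + 1L, j] + params$indel)
    }
  }
  H[length(a) + 1L, length(b) + 1L]
}
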