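#' Alignment scoring parameters
#'
#' Scores used both for scoring a segment against a motif and inside the
#' decomposition dynamic program. Defaults follow the usual convention for
#' motif decomposition: +5 for a match, -4 for a mismatch and -4 per
#' inserted/deleted base (linear gaps).
#'
#' @param match Integer score for a matching base pair; must be positive.
#' @param mismatch Integer score for a mismatching pair; must be less than
#'   `match`.
#' @param indel Integer score for a single-base insertion or deletion; must be
#'   negative.
#' @return An object of class `scoring_params`.
#' @examples
#' scoring_params()
#' scoring_params(match = 2, mismatch = -1, indel = -2)
#' @export
scoring_params <- function(match = 5L, mismatch = -4L, indel = -4L) {
  match <- as.numeric(match)
  mismatch <- as.numeric(mismatch)
  indel <- as.numeric(indel)
  if (!is.finite(match) || match <= 0) {
    stop("`match` must be a positive score", call. = FALSE)
  }
  if (!is.finite(mismatch) || mismatch >= match) {
    stop("`mismatch` must be less than `match`", call. = FALSE)
  }
  if (!is.finite(indel) || indel >= 0) {
    stop("`indel` must be negative", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, indel = indel),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf("Scoring parameters: match %+g, mismatch %+g, indel %+g\n",
              x$match, x$mismatch, x$indel))
  invisible(x)
}

# Uppercase and validate a DNA string. Alleles may contain N (mismatches
# everything); motifs are restricted to ACGT.
.check_dna <- function(x, what, allow_n = TRUE) {
  if (length(x) != 1L || is.na(x) || !is.character(x)) {
    stop(sprintf("`%s` must be a single character string", what), call. = FALSE)
  }
  if (!nzchar(x)) {
    stop(sprintf("`%s` must be a non-empty DNA string", what), call. = FALSE)
  }
  x <- toupper(x)
  ok <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(ok, x)) {
    bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]),
                   if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T"))
    stop(sprintf("`%s` contains invalid characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

.check_params <- function(params) {
  if (!inherits(params, "scoring_params")) {
    params <- do.call(scoring_params, as.list(params))
  }
  params
}

# Global (Needleman-Wunsch) alignment score with linear gap penalties.
# xc, mc: character vectors of single bases. The same-row dependency
# H[j] = max(cand[j], H[j-1] + g) is resolved with a cummax transform so each
# query row is a handful of vectorised operations.
.nw_score_chr <- function(xc, mc, params) {
  g <- params$indel
  k <- length(mc)
  jk <- seq_len(k)
  prev <- g * (0:k)
  for (ch in xc) {
    s <- ifelse(mc == ch & ch != "N", params$match, params$mismatch)
    cand <- pmax(prev[jk] + s, prev[jk + 1L] + g)
    h0 <- prev[1L] + g
    t <- cummax(c(h0, cand - g * jk))
    prev <- c(h0, t[-1L] + g * jk)
  }
  prev[k + 1L]
}

#' Score a segment against a motif
#'
#' Maximum global-alignment score of `x` against `m` under the given
#' match/mismatch/indel scores. This is the per-segment score function used by
#' [decompose_tr()]: identical strings score `match * nchar(x)` and the score
#' is symmetric in its arguments. `N` mismatches every base, including `N`.
#'
#' @param x,m Non-empty DNA strings.
#' @param params A [scoring_params()] object.
#' @return A single numeric score.
#' @examples
#' segment_score("ACCTTG", "ACCTTG")   # 30
#' segment_score("ACCTTTG", "ACCTTG")  # 26: six matches, one insertion
#' @export
segment_score <- function(x, m, params = scoring_params()) {
  params <- .check_params(params)
  x <- .check_dna(x, "x", allow_n = TRUE)
  m <- .check_dna(m, "m", allow_n = TRUE)
  .nw_score_chr(strsplit(x, "", fixed = TRUE)[[1]],
                strsplit(m, "", fixed = TRUE)[[1]], params)
}
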