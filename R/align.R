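#' Motif-similarity scoring matrix over symbols
#'
#' Builds the substitution matrix used to align encoded alleles at the symbol
#' level. The score for two symbols reflects the similarity of the motifs
#' they encode:
#' `score(a, b) = round(s_max - (s_max - s_min) * ed(m_a, m_b) / max(|m_a|, |m_b|))`
#' where `ed` is the unit-cost edit distance, so identical motifs score
#' `s_max` and maximally dissimilar motifs score `s_min`. The private symbol
#' scores `s_min` against everything except itself. Gap penalties are affine;
#' `gap_open` must be below `s_min - 1` so that opening a gap always costs
#' more than the worst mismatch between two retained symbols (gaps are never
#' preferred between similar motifs).
#'
#' @param mapping A [motif_mapping()].
#' @param s_min,s_max Score bounds (defaults 0 and 10).
#' @param gap_open,gap_extend Affine gap penalties (defaults -12, -2).
#' @return An object of class `symbol_score_matrix`: a square numeric matrix
#'   with symbol dimnames (including the private symbol) and attributes
#'   `gap_open`, `gap_extend`, `s_min`, `s_max`.
#' @export
symbol_score_matrix <- function(mapping, s_min = 0, s_max = 10,
                                gap_open = -12, gap_extend = -2) {
  stopifnot(inherits(mapping, "motif_mapping"))
  if (!nrow(mapping$entries) && !nrow(mapping$private)) {
    stop("`mapping` is empty", call. = FALSE)
  }
  if (s_min >= s_max) stop("`s_min` must be less than `s_max`", call. = FALSE)
  if (gap_open >= s_min - 1) {
    stop("`gap_open` must be below s_min - 1 so a gap costs more than any mismatch",
         call. = FALSE)
  }
  if (gap_extend > 0 || gap_extend < gap_open) {
    stop("`gap_extend` must lie in [gap_open, 0]", call. = FALSE)
  }
  syms <- mapping$entries$symbol
  motifs <- mapping$entries$motif
  n <- length(syms)
  M <- matrix(s_min, n + 1L, n + 1L,
              dimnames = list(c(syms, mapping$private_symbol),
                              c(syms, mapping$private_symbol)))
  if (n) {
    ed <- utils::adist(motifs, motifs)
    denom <- outer(nchar(motifs), nchar(motifs), pmax)
    M[seq_len(n), seq_len(n)] <- round(s_max - (s_max - s_min) * ed / denom)
  }
  diag(M) <- s_max
  structure(M, class = c("symbol_score_matrix", "matrix"),
            gap_open = gap_open, gap_extend = gap_extend,
            s_min = s_min, s_max = s_max)
}

# split encoded strings into symbol vectors, validating matrix coverage
.split_symbols <- function(encoded, syms) {
  rows <- strsplit(encoded, "", fixed = TRUE)
  bad <- setdiff(unique(unlist(rows, use.names = FALSE)), syms)
  if (length(bad)) {
    stop("unknown symbol(s) not covered by the score matrix: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  rows
}

## ---- affine-gap (Gotoh) DP over pre-computed column-pair scores ----------
## Three states: M (both columns consumed), X (gap in B, A column consumed),
## Y (gap in A, B column consumed). Rows are vectorised; the same-row
## dependency of Y is resolved with a cummax transform.

.gotoh_fill <- function(S, go, ge) {
  wA <- nrow(S); wB <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, wA + 1L, wB + 1L)
  X <- matrix(NEG, wA + 1L, wB + 1L)
  Y <- matrix(NEG, wA + 1L, wB + 1L)
  M[1L, 1L] <- 0
  if (wB) Y[1L, seq_len(wB) + 1L] <- go + ge * (seq_len(wB) - 1L)
  jb <- seq_len(wB)
  for (i in seq_len(wA)) {
    ip <- i + 1L
    M[ip, jb + 1L] <- S[i, ] + pmax(M[i, jb], X[i, jb], Y[i, jb])
    X[ip, ] <- pmax(pmax(M[i, ], Y[i, ]) + go, X[i, ] + ge)
    open <- pmax(M[ip, jb], X[ip, jb]) + go
    t <- cummax(c(NEG, open - ge * jb))
    Y[ip, jb + 1L] <- t[-1L] + ge * jb
  }
  list(M = M, X = X, Y = Y)
}

.gotoh_score <- function(S, go, ge) {
  f <- .gotoh_fill(S, go, ge)
  max(f$M[nrow(S) + 1L, ncol(S) + 1L],
      f$X[nrow(S) + 1L, ncol(S) + 1L],
      f$Y[nrow(S) + 1L, ncol(S) + 1L])
}

# Returns the optimal score and the merged column operations:
# "D" = consume a column of each profile, "A" = A column against a gap,
# "B" = B column against a gap.
.gotoh_align <- function(S, go, ge) {
  wA <- nrow(S); wB <- ncol(S)
  f <- .gotoh_fill(S, go, ge)
  M <- f$M; X <- f$X; Y <- f$Y
  ends <- c(M[wA + 1L, wB + 1L], X[wA + 1L, wB + 1L], Y[wA + 1L, wB + 1L])
  state <- which.max(ends + c(2e-7, 1e-7, 0))  # prefer M, then X, then Y
  score <- ends[state]
  tol <- 1e-6
  ops <- character(wA + wB)
  np <- 0L
  i <- wA; j <- wB
  while (i > 0L || j > 0L) {
    np <- np + 1L
    if (state == 1L) {
      ops[np] <- "D"
      tgt <- M[i + 1L, j + 1L] - S[i, j]
      i <- i - 1L; j <- j - 1L
      prev <- c(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L])
      state <- which(abs(prev - tgt) < tol)[1L]
    } else if (state == 2L) {
      ops[np] <- "A"
      val <- X[i + 1L, j + 1L]
      i <- i - 1L
      cand <- c(M[i + 1L, j + 1L] + go, X[i + 1L, j + 1L] + ge,
                Y[i + 1L, j + 1L] + go)
      state <- which(abs(cand - val) < tol)[1L]
    } else {
      ops[np] <- "B"
      val <- Y[i + 1L, j + 1L]
      j <- j - 1L
      cand <- c(M[i + 1L, j + 1L] + go, X[i + 1L, j + 1L] + go,
                Y[i + 1L, j + 1L] + ge)
      state <- which(abs(cand - val) < tol)[1L]
    }
    if (is.na(state)) stop("internal error: alignment traceback failed")
  }
  list(score = score, ops = rev(ops[seq_len(np)]))
}

# column frequency matrix of a profile (rows x width character matrix):
# width x nsym, proportions over all rows (gaps contribute nothing)
.profile_freq <- function(prof, syms) {
  nr <- nrow(prof)
  F <- matrix(0, ncol(prof), length(syms), dimnames = list(NULL, syms))
  for (s in unique(as.vector(prof))) {
    if (s == gap_symbol()) next
    F[, s] <- colSums(prof == s) / nr
  }
  F
}

# merge two profiles along a column-operation path
.merge_profiles <- function(A, B, ops) {
  L <- length(ops)
  out <- matrix(gap_symbol(), nrow(A) + nrow(B), L)
  rownames(out) <- c(rownames(A), rownames(B))
  out[seq_len(nrow(A)), ops != "B"] <- A
  out[nrow(A) + seq_len(nrow(B)), ops != "A"] <- B
  out
}

#' Multiple alignment of encoded alleles
#'
#' Progressive multiple sequence alignment over the symbol alphabet: pairwise
#' global alignment scores give normalized distances, an average-linkage
#' guide tree orders the merges, and profiles are merged by profile-profile
#' alignment with affine gap penalties ("once a gap, always a gap").
#' Deterministic for a fixed input order. For two sequences this reduces
#' exactly to optimal pairwise global alignment.
#'
#' @param encoded Named character vector of encoded alleles (symbol strings).
#' @param matrix A [symbol_score_matrix()].
#' @return An object of class `encoded_alignment`: list with `rows` (named
#'   character vector of gap-padded symbol strings, input order), `width`,
#'   and `score` (the objective value of the final profile merge; `NA` for a
#'   single sequence). Removing gaps from row i reproduces `encoded[i]`.
#' @examples
#' d <- decompose_alleles(c(a = "ACGACGACG", b = "ACGACG"), "ACG")
#' m <- motif_mapping(d, 1)
#' align_encoded(encode_alleles(d, m), symbol_score_matrix(m))
#' @export
align_encoded <- function(encoded, matrix) {
  stopifnot(inherits(matrix, "symbol_score_matrix"))
  if (!length(encoded)) stop("`encoded` must contain at least one sequence", call. = FALSE)
  ids <- names(encoded)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("`encoded` must have unique non-empty names", call. = FALSE)
  }
  syms <- rownames(matrix)
  go <- attr(matrix, "gap_open"); ge <- attr(matrix, "gap_extend")
  Mnum <- base::matrix(as.numeric(matrix), nrow(matrix), ncol(matrix),
                       dimnames = dimnames(matrix))
  chrs <- .split_symbols(encoded, syms)
  n <- length(encoded)

  if (n == 1L) {
    return(structure(list(rows = stats::setNames(unname(encoded), ids),
                          width = nchar(encoded[[1L]]), score = NA_real_),
                     class = "encoded_alignment"))
  }

  idx <- lapply(chrs, function(ch) match(ch, syms))
  s_max <- attr(matrix, "s_max")
  self <- vapply(idx, function(a) sum(Mnum[cbind(a, a)]), 0)

  ## guide tree on normalized pairwise alignment distances
  D <- base::matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      S <- Mnum[idx[[a]], idx[[b]], drop = FALSE]
      sc <- .gotoh_score(S, go, ge)
      D[a, b] <- D[b, a] <- 1 - 2 * sc / (self[a] + self[b])
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  profiles <- vector("list", n - 1L)
  get_prof <- function(node) {
    if (node < 0L) {
      p <- base::matrix(chrs[[-node]], 1L)
      rownames(p) <- ids[-node]
      p
    } else profiles[[node]]
  }
  score <- NA_real_
  for (k in seq_len(n - 1L)) {
    A <- get_prof(hc$merge[k, 1L])
    B <- get_prof(hc$merge[k, 2L])
    S <- .profile_freq(A, syms) %*% Mnum %*% t(.profile_freq(B, syms))
    al <- .gotoh_align(S, go, ge)
    profiles[[k]] <- .merge_profiles(A, B, al$ops)
    score <- al$score
  }
  final <- profiles[[n - 1L]]
  final <- final[ids, , drop = FALSE]
  keep <- colSums(final != gap_symbol()) > 0L
  final <- final[, keep, drop = FALSE]

  structure(list(rows = stats::setNames(apply(final, 1L, paste, collapse = ""), ids),
                 width = ncol(final), score = score),
            class = "encoded_alignment")
}

#' @export
print.encoded_alignment <- function(x, ...) {
  cat(sprintf("Encoded alignment: %d alleles, width %d\n", length(x$rows), x$width))
  show <- utils::head(x$rows, 8L)
  cat(sprintf("  %-12s %s\n", names(show), show), sep = "")
  if (length(x$rows) > 8L) cat(sprintf("  ... %d more rows\n", length(x$rows) - 8L))
  invisible(x)
}

# gapped rows as a character matrix (one column per alignment column)
.alignment_matrix <- function(a) {
  stopifnot(inherits(a, "encoded_alignment"))
  m <- do.call(rbind, strsplit(unname(a$rows), "", fixed = TRUE))
  rownames(m) <- names(a$rows)
  m
}
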