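#' Optimally parse a tandem repeat allele into motif segments
#'
#' Partitions the allele `x` into consecutive segments, each globally aligned
#' to the best-matching motif, so that the summed alignment score is maximal.
#' The dynamic program tracks, for every query prefix and every motif
#' position, the best score of a parse whose current segment is aligned up to
#' that motif position; a completed motif may hand over to the start of any
#' motif, so motifs chain freely. Segments whose substring matches no supplied
#' motif are emitted as novel motifs.
#'
#' Ties between co-optimal segmentations are broken deterministically: an
#' exact segment (substring equal to its motif) wins over an inexact one, then
#' the motif earliest in the supplied order, then the longer segment.
#'
#' @param x A non-empty DNA string (the tandem repeat region only; `N`
#'   allowed, mismatching everything).
#' @param motifs Character vector of distinct, non-empty ACGT motifs.
#' @param params A [scoring_params()] object.
#' @param allele_id Identifier stored in the result.
#' @return An object of class `tr_decomposition`: a list with `allele_id`,
#'   `segments` (a data.frame with 0-based `segment_index`, `substring`,
#'   `aligned_motif`, `segment_score`, `is_exact`, `origin`), `total_score`
#'   and `input_motifs`. The substrings concatenate to `x` exactly.
#' @examples
#' d <- decompose_tr("ACCTTGACCTTGACCTTTG", "ACCTTG")
#' d$segments$substring  # "ACCTTG" "ACCTTG" "ACCTTTG"
#' d$total_score         # 86
#' @seealso [decompose_alleles()] for a batch of alleles,
#'   [brute_force_decompose()] for the exhaustive oracle.
#' @export
decompose_tr <- function(x, motifs, params = scoring_params(),
                         allele_id = "allele") {
  params <- .check_params(params)
  x <- .check_dna(x, "x", allow_n = TRUE)
  motifs <- .check_motifs(motifs)

  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(xc)
  mchars <- lapply(motifs, function(m) strsplit(m, "", fixed = TRUE)[[1]])
  g <- params$indel

  ## Forward pass: B[i+1] = best score of a complete parse of x[1..i].
  ## rows[[u]][j+1] = best score of a parse of the consumed prefix whose
  ## open segment is aligned to motif u up to position j.
  nm <- length(motifs)
  rows <- lapply(mchars, function(mc) cumsum(c(0, rep(g, length(mc)))))
  B <- numeric(n + 1L)
  for (i in seq_len(n)) {
    best <- -Inf
    for (u in seq_len(nm)) {
      mc <- mchars[[u]]
      k <- length(mc)
      jk <- seq_len(k)
      prev <- rows[[u]]
      s <- ifelse(mc == xc[i] & xc[i] != "N", params$match, params$mismatch)
      cand <- pmax(prev[jk] + s, prev[jk + 1L] + g)
      h0 <- prev[1L] + g
      t <- cummax(c(h0, cand - g * jk))
      r <- c(h0, t[-1L] + g * jk)
      rows[[u]] <- r
      if (r[k + 1L] > best) best <- r[k + 1L]
    }
    B[i + 1L] <- best
    # A new segment may start after position i: seed motif position 0 with
    # the completed-parse score and re-propagate leading motif deletions.
    for (u in seq_len(nm)) {
      r <- rows[[u]]
      if (best > r[1L]) {
        k <- length(r) - 1L
        jk <- seq_len(k)
        t <- cummax(c(best, r[-1L] - g * jk))
        rows[[u]] <- c(best, t[-1L] + g * jk)
      }
    }
  }

  ## Backtrack segment by segment. For the segment ending at `pos`, a reverse
  ## DP against each motif yields the score of aligning every suffix window
  ## x[(s+1)..pos]; boundaries with B[s] + window score == B[pos] are the
  ## co-optimal cuts.
  seg_sub <- character(0)
  seg_motif <- character(0)
  seg_score <- numeric(0)
  pos <- n
  while (pos > 0L) {
    cand_s <- integer(0); cand_u <- integer(0); cand_g <- numeric(0)
    for (u in seq_len(nm)) {
      gs <- .nw_suffix_scores(xc, mchars[[u]], params, pos)
      hit <- which(abs(B[seq_len(pos)] + gs - B[pos + 1L]) < 1e-9)
      if (length(hit)) {
        cand_s <- c(cand_s, hit - 1L)
        cand_u <- c(cand_u, rep(u, length(hit)))
        cand_g <- c(cand_g, gs[hit])
      }
    }
    if (!length(cand_s)) stop("internal error: backtracking found no cut")
    subs <- substr(rep(x, length(cand_s)), cand_s + 1L, pos)
    exact <- subs == motifs[cand_u]
    # tie-break: exact first, then earliest motif, then longer segment
    pick <- order(!exact, cand_u, cand_s)[1L]
    seg_sub <- c(subs[pick], seg_sub)
    seg_motif <- c(motifs[cand_u[pick]], seg_motif)
    seg_score <- c(cand_g[pick], seg_score)
    pos <- cand_s[pick]
  }

  segments <- data.frame(
    segment_index = seq_along(seg_sub) - 1L,
    substring = seg_sub,
    aligned_motif = seg_motif,
    segment_score = seg_score,
    is_exact = seg_sub == seg_motif,
    origin = ifelse(seg_sub %in% motifs, "input", "novel"),
    stringsAsFactors = FALSE
  )
  stopifnot(identical(paste(seg_sub, collapse = ""), x))

  structure(list(allele_id = allele_id, segments = segments,
                 total_score = B[n + 1L], input_motifs = motifs),
            class = "tr_decomposition")
}

# Reverse NW: returns gs[t] = global alignment score of x[t..end] vs motif mc,
# for t = 1..end. Vectorised over motif positions with the reverse cummax
# transform for the same-row (motif deletion) dependency.
.nw_suffix_scores <- function(xc, mc, params, end) {
  g <- params$indel
  k <- length(mc)
  jk <- seq_len(k)
  nxt <- g * (k:0)            # nxt[j] = score of aligning empty suffix to m[j..k]
  gs <- numeric(end)
  for (t in end:1) {
    s <- ifelse(mc == xc[t] & xc[t] != "N", params$match, params$mismatch)
    cand <- pmax(nxt[jk + 1L] + s, nxt[jk] + g)
    rlast <- nxt[k + 1L] + g
    u <- rev(cummax(rev(c(cand + g * jk, rlast + g * (k + 1L)))))
    nxt <- c(u[jk] - g * jk, rlast)
    gs[t] <- nxt[1L]
  }
  gs
}

.check_motifs <- function(motifs) {
  if (inherits(motifs, "data.frame")) motifs <- motifs$motif
  motifs <- as.character(motifs)
  if (!length(motifs)) stop("`motifs` must contain at least one motif", call. = FALSE)
  motifs <- vapply(motifs, .check_dna, "", what = "motifs", allow_n = FALSE,
                   USE.NAMES = FALSE)
  if (anyDuplicated(motifs)) {
    stop("duplicate motifs: ",
         paste(unique(motifs[duplicated(motifs)]), collapse = ", "),
         call. = FALSE)
  }
  motifs
}

#' Decompose a batch of alleles
#'
#' Runs [decompose_tr()] over a set of named alleles, preserving input order,
#' and collects the novel motifs discovered across all alleles into an
#' augmented motif set. Novel motifs are not fed back into the motif set for
#' re-parsing (single-pass behaviour).
#'
#' @param alleles Named character vector of DNA strings; names are allele ids
#'   and must be unique.
#' @param motifs Character vector of input motifs.
#' @param params A [scoring_params()] object.
#' @return An object of class `tr_decomposition_set`: a list with
#'   `decompositions` (named list of `tr_decomposition`) and `motif_set`
#'   (data.frame `motif`, `origin` with origin `"input"` or `"novel"`).
#' @examples
#' decompose_alleles(c(a = "ACGACG", b = "ACGACG"), "ACG")
#' @export
decompose_alleles <- function(alleles, motifs, params = scoring_params()) {
  params <- .check_params(params)
  ids <- names(alleles)
  if (length(alleles) && (is.null(ids) || any(!nzchar(ids)))) {
    stop("`alleles` must be a named character vector", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate allele ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  motifs <- .check_motifs(motifs)
  decs <- vector("list", length(alleles))
  names(decs) <- ids
  novel <- character(0)
  for (i in seq_along(alleles)) {
    d <- decompose_tr(alleles[[i]], motifs, params, allele_id = ids[i])
    decs[[i]] <- d
    nv <- d$segments$substring[d$segments$origin == "novel"]
    novel <- c(novel, setdiff(nv, novel))
  }
  motif_set <- data.frame(
    motif = c(motifs, novel),
    origin = c(rep("input", length(motifs)), rep("novel", length(novel))),
    stringsAsFactors = FALSE
  )
  structure(list(decompositions = decs, motif_set = motif_set, params = params),
            class = "tr_decomposition_set")
}

#' @export
print.tr_decomposition <- function(x, ...) {
  cat(sprintf("Tandem repeat decomposition of '%s': %d segments, total score %g\n",
              x$allele_id, nrow(x$segments), x$total_score))
  cat("  ", paste(x$segments$substring, collapse = " | "), "\n", sep = "")
  nov <- unique(x$segments$substring[x$segments$origin == "novel"])
  if (length(nov)) cat("  novel motifs: ", paste(nov, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.tr_decomposition_set <- function(x, ...) {
  nseg <- sum(vapply(x$decompositions, function(d) nrow(d$segments), 0L))
  cat(sprintf("Decompositions of %d alleles: %d segments, %d input + %d novel motifs\n",
              length(x$decompositions), nseg,
              sum(x$motif_set$origin == "input"),
              sum(x$motif_set$origin == "novel")))
  invisible(x)
}
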