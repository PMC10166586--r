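#' Reorder aligned alleles so similar alleles are adjacent
#'
#' Computes a display order for the rows of an [align_encoded()] alignment.
#' The default clusters rows hierarchically (average linkage) on the fraction
#' of alignment columns at which two rows differ (a gap against a symbol
#' counts as a difference) and reads the leaf order off the dendrogram, with
#' subtree ties broken deterministically: the smaller subtree first, then the
#' subtree containing the lexicographically smallest id. Alternative orders:
#' ascending motif count (non-gap symbols), ascending allele length,
#' lexicographic id order, or a manual permutation.
#'
#' @param a An `encoded_alignment`.
#' @param method One of `"clustering"`, `"motif_count"`, `"length"`,
#'   `"lexicographic"`, `"manual"`.
#' @param manual_order Character vector: a permutation of the alignment's
#'   ids; required for `method = "manual"`.
#' @param allele_lengths Named numeric vector of allele (nucleotide) lengths;
#'   required for `method = "length"`.
#' @return An object of class `row_order`: list with `order` (permutation of
#'   allele ids) and `method`.
#' @export
rearrange_rows <- function(a,
                           method = c("clustering", "motif_count", "length",
                                      "lexicographic", "manual"),
                           manual_order = NULL, allele_lengths = NULL) {
  stopifnot(inherits(a, "encoded_alignment"))
  method <- match.arg(method)
  ids <- names(a$rows)
  ord <- switch(method,
    clustering = .cluster_order(a, ids),
    motif_count = {
      counts <- nchar(gsub(gap_symbol(), "", a$rows, fixed = TRUE))
      ids[order(counts, ids, method = "radix")]
    },
    length = {
      if (is.null(allele_lengths)) {
        stop("method = \"length\" needs `allele_lengths` (named, one per allele)",
             call. = FALSE)
      }
      if (!all(ids %in% names(allele_lengths))) {
        stop("`allele_lengths` is missing ids: ",
             paste(setdiff(ids, names(allele_lengths)), collapse = ", "),
             call. = FALSE)
      }
      ids[order(allele_lengths[ids], ids, method = "radix")]
    },
    lexicographic = ids[order(ids, method = "radix")],
    manual = {
      if (is.null(manual_order)) {
        stop("method = \"manual\" needs `manual_order`", call. = FALSE)
      }
      missing <- setdiff(ids, manual_order)
      extra <- setdiff(manual_order, ids)
      if (length(missing) || length(extra) || length(manual_order) != length(ids)) {
        stop("`manual_order` is not a permutation of the alignment ids",
             if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
             if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
             call. = FALSE)
      }
      manual_order
    }
  )
  structure(list(order = ord, method = method), class = "row_order")
}

.cluster_order <- function(a, ids) {
  n <- length(ids)
  if (n == 1L) return(ids)
  m <- .alignment_matrix(a)
  D <- base::matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- mean(m[i, ] != m[j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # deterministic leaf order: smaller subtree first, ties by smallest id
  walk <- function(node) {
    if (node < 0L) return(ids[-node])
    l <- walk(hc$merge[node, 1L])
    r <- walk(hc$merge[node, 2L])
    swap <- length(r) < length(l) ||
      (length(r) == length(l) && .radix_lt(.radix_min(r), .radix_min(l)))
    if (swap) c(r, l) else c(l, r)
  }
  walk(nrow(hc$merge))
}

.radix_min <- function(x) sort(x, method = "radix")[1L]

# locale-free string comparison: is a strictly before b in byte order?
.radix_lt <- function(a, b) a != b && sort(c(a, b), method = "radix")[1L] == a

#' @export
print.row_order <- function(x, ...) {
  cat(sprintf("Row order (%s): %s\n", x$method,
              paste(utils::head(x$order, 12L), collapse = ", ")))
  if (length(x$order) > 12L) cat(sprintf("  ... %d more\n", length(x$order) - 12L))
  invisible(x)
}

#' Write a row order as a plain-text id list
#'
#' @param order A `row_order`.
#' @param path File path; one allele id per line.
#' @return `path`, invisibly.
#' @export
write_row_order <- function(order, path) {
  stopifnot(inherits(order, "row_order"))
  writeLines(order$order, path)
  invisible(path)
}
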