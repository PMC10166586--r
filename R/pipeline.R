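#' Full motif-composition analysis of a set of tandem repeat alleles
#'
#' Runs the four analysis stages in order — decomposition into motif
#' segments, symbol encoding, multiple alignment of the encoded alleles, and
#' row rearrangement — and returns everything needed to render or inspect
#' the motif composition. Each stage is also available as a standalone
#' function ([decompose_alleles()], [motif_mapping()], [align_encoded()],
#' [rearrange_rows()]).
#'
#' @param alleles Named character vector of DNA strings (e.g. from
#'   [read_alleles()]).
#' @param motifs Character vector of input motifs.
#' @param params [scoring_params()] for the decomposition.
#' @param threshold Private-motif frequency threshold, or `"auto"`.
#' @param s_min,s_max,gap_open,gap_extend Symbol alignment parameters, see
#'   [symbol_score_matrix()].
#' @param sort Row rearrangement method, see [rearrange_rows()].
#' @param manual_order Optional explicit row order (for `sort = "manual"`).
#' @param annotations Optional named character vector of group labels.
#' @return An object of class `tr_composition`: list with `decomposition`
#'   (`tr_decomposition_set`), `mapping`, `encoded`, `score_matrix`,
#'   `alignment`, `order`, `colors`, `annotations` and `alleles`.
#' @examples
#' res <- tr_composition(c(a = "ACGACGACG", b = "ACGACTACG"), "ACG")
#' summary(res)
#' @export
tr_composition <- function(alleles, motifs, params = scoring_params(),
                           threshold = "auto", s_min = 0, s_max = 10,
                           gap_open = -12, gap_extend = -2,
                           sort = "clustering", manual_order = NULL,
                           annotations = NULL) {
  if (!length(alleles)) stop("no alleles supplied", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dec <- stage("decompose", decompose_alleles(alleles, motifs, params))
  mapping <- stage("encode", motif_mapping(dec, threshold))
  encoded <- stage("encode", encode_alleles(dec, mapping))
  smat <- stage("align", symbol_score_matrix(mapping, s_min, s_max,
                                             gap_open, gap_extend))
  aln <- stage("align", align_encoded(encoded, smat))
  ord <- stage("rearrange",
               rearrange_rows(aln, sort, manual_order = manual_order,
                              allele_lengths = stats::setNames(nchar(alleles),
                                                               names(alleles))))
  colors <- stage("render", assign_symbol_colors(mapping))
  structure(list(alleles = alleles, decomposition = dec, mapping = mapping,
                 encoded = encoded, score_matrix = smat, alignment = aln,
                 order = ord, colors = colors, annotations = annotations),
            class = "tr_composition")
}

#' @export
print.tr_composition <- function(x, ...) {
  cat(sprintf("Motif composition of %d tandem repeat alleles\n",
              length(x$alleles)))
  cat(sprintf("  motifs: %d input, %d novel, %d private; alignment width %d; order: %s\n",
              sum(x$decomposition$motif_set$origin == "input"),
              sum(x$decomposition$motif_set$origin == "novel"),
              nrow(x$mapping$private), x$alignment$width, x$order$method))
  invisible(x)
}

#' @export
summary.tr_composition <- function(object, ...) {
  segs <- vapply(object$decomposition$decompositions,
                 function(d) nrow(d$segments), 0L)
  out <- list(
    n_alleles = length(object$alleles),
    allele_length = range(nchar(object$alleles)),
    motif_counts = range(segs),
    n_symbols = nrow(object$mapping$entries),
    n_private = nrow(object$mapping$private),
    width = object$alignment$width,
    motif_table = object$mapping$entries
  )
  class(out) <- "summary.tr_composition"
  out
}

#' @export
print.summary.tr_composition <- function(x, ...) {
  cat(sprintf("%d alleles, %d-%d bp, %d-%d motif copies\n", x$n_alleles,
              x$allele_length[1], x$allele_length[2],
              x$motif_counts[1], x$motif_counts[2]))
  cat(sprintf("%d motif symbols (+%d private motifs), alignment width %d\n",
              x$n_symbols, x$n_private, x$width))
  print(utils::head(x$motif_table, 15L), row.names = FALSE)
  invisible(x)
}

#' @export
plot.tr_composition <- function(x, ...) {
  .draw_composition(x$alignment, x$order, x$colors, x$annotations, ...)
}

#' Pipeline run configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Motifs may be
#' given inline or as a one-per-line file; exactly one of the two is
#' required.
#'
#' @param fasta Path to the input allele FASTA.
#' @param motifs Character vector of motifs (alternative to `motif_file`).
#' @param motif_file Path to a one-per-line motif file.
#' @param out_dir Output directory (created if missing).
#' @param params [scoring_params()].
#' @param threshold Private-motif threshold or `"auto"`.
#' @param sort Rearrangement method.
#' @param annotation_file Optional sample annotation TSV (`sample`, `group`).
#' @param format Figure format: `"svg"`, `"png"` or `"pdf"`.
#' @param seed Integer seed stored in the config; the pipeline itself is
#'   deterministic, the seed covers any downstream randomized additions.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta, motifs = NULL, motif_file = NULL,
                       out_dir = ".", params = scoring_params(),
                       threshold = "auto", sort = "clustering",
                       annotation_file = NULL, format = "svg", seed = 1L) {
  if (is.null(motifs) == is.null(motif_file)) {
    stop("supply exactly one of `motifs` or `motif_file`", call. = FALSE)
  }
  if (!file.exists(fasta)) stop("input FASTA not found: ", fasta, call. = FALSE)
  if (!is.null(motif_file)) {
    if (!file.exists(motif_file)) stop("motif file not found: ", motif_file,
                                       call. = FALSE)
    motifs <- read_motifs(motif_file)
  } else {
    motifs <- .check_motifs(motifs)
  }
  if (!is.null(annotation_file) && !file.exists(annotation_file)) {
    stop("annotation file not found: ", annotation_file, call. = FALSE)
  }
  format <- match.arg(format, c("svg", "png", "pdf"))
  structure(list(fasta = fasta, motifs = motifs, out_dir = out_dir,
                 params = .check_params(params), threshold = threshold,
                 sort = sort, annotation_file = annotation_file,
                 format = format, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline and write all artifacts
#'
#' Executes decompose, encode, align, rearrange and render in order and
#' writes six artifacts into `cfg$out_dir`: `decomposition.tsv`,
#' `motif_mapping.tsv`, `alignment.fasta`, `row_order.txt`,
#' `composition.<format>` and `motif_table.tsv`. Output is deterministic:
#' the same configuration always produces byte-identical text artifacts.
#' Stage progress and timings are logged to stderr.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress the stderr log.
#' @return Invisibly, a list with the `tr_composition` result and the named
#'   vector of artifact `paths`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  log <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    log("[%s] done in %.2fs", stage, t1 - t0)
    t0 <<- t1
  }
  set.seed(cfg$seed)
  alleles <- read_alleles(cfg$fasta)
  annotations <- if (!is.null(cfg$annotation_file)) {
    read_annotations(cfg$annotation_file)
  }
  log("[input] %d alleles, %d motifs", length(alleles), length(cfg$motifs))
  res <- tr_composition(alleles, cfg$motifs, params = cfg$params,
                        threshold = cfg$threshold, sort = cfg$sort,
                        annotations = annotations)
  tick("pipeline")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    decomposition = file.path(cfg$out_dir, "decomposition.tsv"),
    mapping = file.path(cfg$out_dir, "motif_mapping.tsv"),
    alignment = file.path(cfg$out_dir, "alignment.fasta"),
    order = file.path(cfg$out_dir, "row_order.txt"),
    figure = file.path(cfg$out_dir, paste0("composition.", cfg$format)),
    motif_table = file.path(cfg$out_dir, "motif_table.tsv")
  )
  write_decomposition_tsv(res$decomposition, paths[["decomposition"]])
  write_mapping(res$mapping, paths[["mapping"]])
  write_alignment_fasta(res$alignment, paths[["alignment"]], res$order)
  write_row_order(res$order, paths[["order"]])
  render_composition(res$alignment, res$order, res$colors, res$mapping,
                     res$annotations, paths[["figure"]], cfg$format)
  write_motif_table(res$mapping, res$colors, paths[["motif_table"]])
  tick("write")
  invisible(list(result = res, paths = paths))
}
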