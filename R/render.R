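#' Assign a color to every motif symbol
#'
#' Deterministic palette: evenly spaced HSV hues (fixed saturation and value)
#' assigned by symbol rank, so the most frequent motif always receives the
#' first hue and repeated runs give identical colors. The private symbol is
#' grey.
#'
#' @param mapping A [motif_mapping()].
#' @param private_color Color for the private symbol (default grey).
#' @return Named character vector of hex colors, one per symbol (including
#'   the private symbol); all non-private colors are distinct.
#' @export
assign_symbol_colors <- function(mapping, private_color = "#9E9E9E") {
  stopifnot(inherits(mapping, "motif_mapping"))
  n <- nrow(mapping$entries)
  cols <- character(0)
  if (n) {
    cols <- grDevices::hsv((seq_len(n) - 1L) / n, s = 0.62, v = 0.92)
    # hue spacing guarantees distinctness up to 90 symbols; guard regardless
    while (anyDuplicated(cols)) {
      i <- which(duplicated(cols))[1L]
      cols[i] <- grDevices::hsv((i - 0.5) / n, s = 0.62, v = 0.85)
    }
  }
  stats::setNames(c(cols, private_color),
                  c(mapping$entries$symbol, mapping$private_symbol))
}

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# deterministic colors for group labels (Okabe-Ito first, then hues)
.group_colors <- function(groups) {
  u <- sort(unique(groups), method = "radix")
  base <- grDevices::palette.colors(n = min(length(u), 8L), palette = "Okabe-Ito",
                                    recycle = FALSE)
  extra <- if (length(u) > 8L) {
    grDevices::hsv((seq_len(length(u) - 8L) - 1L) / (length(u) - 8L), 0.4, 0.7)
  } else character(0)
  stats::setNames(c(unname(base), extra), u)
}

#' Render the motif-composition figure as SVG
#'
#' One horizontal band per allele in the given row order; each non-gap
#' alignment column is drawn as a colored cell (`class="cell"`), gaps as
#' empty space. Sample names label each band; an optional group annotation
#' is drawn as a color patch beside the name. A legend maps colors to motif
#' sequences and counts. The SVG is hand-written, so its structure is
#' machine-checkable: bands are `<g class="allele">` elements.
#'
#' @param a An `encoded_alignment`.
#' @param order A `row_order` covering the alignment (default: input order).
#' @param colors Symbol color map from [assign_symbol_colors()].
#' @param mapping Optional [motif_mapping()] used for the legend (motif
#'   sequences and counts).
#' @param annotations Optional named character vector mapping allele ids to
#'   group labels.
#' @param file Output path.
#' @param cell_w,cell_h Cell geometry in pixels.
#' @return `file`, invisibly.
#' @export
write_composition_svg <- function(a, order = NULL, colors, mapping = NULL,
                                  annotations = NULL, file,
                                  cell_w = 14, cell_h = 14) {
  stopifnot(inherits(a, "encoded_alignment"))
  ids <- if (is.null(order)) names(a$rows) else order$order
  if (!setequal(ids, names(a$rows)) || length(ids) != length(a$rows)) {
    stop("`order` does not cover the alignment rows", call. = FALSE)
  }
  m <- .alignment_matrix(a)[ids, , drop = FALSE]
  present <- setdiff(unique(as.vector(m)), gap_symbol())
  missing_col <- setdiff(present, names(colors))
  if (length(missing_col)) {
    stop("no color for symbol(s): ", paste(missing_col, collapse = " "),
         call. = FALSE)
  }

  has_groups <- !is.null(annotations) && length(annotations) > 0L
  gcols <- if (has_groups) .group_colors(unname(annotations)) else NULL
  name_w <- 8 * max(nchar(ids)) + 10
  group_w <- if (has_groups) cell_h + 6 else 0
  left <- name_w + group_w
  n <- length(ids); w <- a$width

  legend <- NULL
  if (!is.null(mapping)) {
    ent <- mapping$entries[mapping$entries$symbol %in% present, , drop = FALSE]
    legend <- ent
    if (nrow(mapping$private) && mapping$private_symbol %in% present) {
      legend <- rbind(legend, data.frame(
        symbol = mapping$private_symbol,
        motif = sprintf("private (%d motifs)", nrow(mapping$private)),
        count = sum(mapping$private$count), stringsAsFactors = FALSE))
    }
  }
  legend_h <- if (is.null(legend)) 0 else nrow(legend) * (cell_h + 4) + 20

  total_w <- left + w * cell_w + 20
  total_h <- n * (cell_h + 2) + 20 + legend_h
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            ceiling(total_w), ceiling(total_h)),
    '<style>text{font-family:monospace;font-size:10px;}</style>'
  )
  for (r in seq_len(n)) {
    y <- 10 + (r - 1) * (cell_h + 2)
    row <- m[r, ]
    band <- sprintf('<g class="allele" data-id="%s">', .svg_escape(ids[r]))
    band <- c(band, sprintf(
      '<text x="%g" y="%g">%s</text>', 2, y + cell_h - 3, .svg_escape(ids[r])))
    if (has_groups && ids[r] %in% names(annotations)) {
      band <- c(band, sprintf(
        '<rect class="group" x="%g" y="%g" width="%g" height="%g" fill="%s"/>',
        name_w, y, cell_h, cell_h, gcols[[annotations[[ids[r]]]]]))
    }
    cols <- which(row != gap_symbol())
    if (length(cols)) {
      band <- c(band, sprintf(
        '<rect class="cell" x="%g" y="%g" width="%g" height="%g" fill="%s"><title>%s</title></rect>',
        left + (cols - 1) * cell_w, y, cell_w - 1, cell_h,
        colors[row[cols]], .svg_escape(row[cols])))
    }
    out <- c(out, band, "</g>")
  }
  if (!is.null(legend)) {
    y0 <- n * (cell_h + 2) + 28
    out <- c(out, '<g class="legend">',
             sprintf('<text x="2" y="%g">Motifs</text>', y0 - 6))
    for (k in seq_len(nrow(legend))) {
      y <- y0 + (k - 1) * (cell_h + 4)
      fill <- if (legend$symbol[k] == private_symbol()) {
        colors[[private_symbol()]]
      } else colors[[legend$symbol[k]]]
      out <- c(out, sprintf(
        '<g class="legend-entry"><rect x="2" y="%g" width="%g" height="%g" fill="%s"/><text x="%g" y="%g">%s %s (n=%d)</text></g>',
        y, cell_w, cell_h, fill, cell_w + 8, y + cell_h - 3,
        .svg_escape(legend$symbol[k]), .svg_escape(legend$motif[k]),
        legend$count[k]))
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  writeLines(out, file)
  invisible(file)
}

#' Write the motif color/frequency table
#'
#' TSV companion of the figure legend: one row per non-private symbol plus
#' one per private motif, with columns `symbol`, `motif`, `count`, `color`.
#'
#' @param mapping A [motif_mapping()].
#' @param colors Color map from [assign_symbol_colors()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(mapping, colors, path) {
  stopifnot(inherits(mapping, "motif_mapping"))
  rows <- rbind(
    cbind(mapping$entries, color = unname(colors[mapping$entries$symbol])),
    if (nrow(mapping$private))
      data.frame(symbol = mapping$private_symbol, motif = mapping$private$motif,
                 count = mapping$private$count,
                 color = unname(colors[mapping$private_symbol]),
                 stringsAsFactors = FALSE)
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# draw the composition on the active graphics device (base graphics);
# used by plot.tr_composition and the PNG/PDF output formats
.draw_composition <- function(a, order, colors, annotations = NULL,
                              main = "Motif composition") {
  ids <- order$order
  m <- .alignment_matrix(a)[ids, , drop = FALSE]
  n <- length(ids); w <- ncol(m)
  has_groups <- !is.null(annotations) && length(annotations) > 0L
  gcols <- if (has_groups) .group_colors(unname(annotations)) else NULL
  op <- graphics::par(mar = c(2, 8, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(if (has_groups) -1.5 else 0, w),
                 ylim = c(n, 0), xlab = "", ylab = "", axes = FALSE,
                 main = main, xaxs = "i", yaxs = "i")
  graphics::axis(2, at = seq_len(n) - 0.5, labels = ids, las = 2, tick = FALSE,
                 cex.axis = 0.6)
  for (r in seq_len(n)) {
    if (has_groups && ids[r] %in% names(annotations)) {
      graphics::rect(-1.4, r - 0.95, -0.4, r - 0.05,
                     col = gcols[[annotations[[ids[r]]]]], border = NA)
    }
    cols <- which(m[r, ] != gap_symbol())
    if (length(cols)) {
      graphics::rect(cols - 1, r - 0.95, cols - 0.08, r - 0.05,
                     col = colors[m[r, cols]], border = NA)
    }
  }
  invisible(NULL)
}

#' Render the motif-composition figure
#'
#' Dispatches on output format: `"svg"` writes the hand-built, testable SVG
#' ([write_composition_svg()]); `"png"` and `"pdf"` draw the same layout on
#' the corresponding grDevices device.
#'
#' @inheritParams write_composition_svg
#' @param format One of `"svg"`, `"png"`, `"pdf"`.
#' @return `file`, invisibly.
#' @export
render_composition <- function(a, order = NULL, colors, mapping = NULL,
                               annotations = NULL, file,
                               format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  if (is.null(order)) {
    order <- structure(list(order = names(a$rows), method = "manual"),
                       class = "row_order")
  }
  if (format == "svg") {
    return(write_composition_svg(a, order, colors, mapping, annotations, file))
  }
  n <- length(a$rows)
  h <- max(3, 0.18 * n + 1.5); wd <- max(5, 0.16 * a$width + 2.5)
  if (format == "png") {
    grDevices::png(file, width = wd, height = h, units = "in", res = 150)
  } else {
    grDevices::pdf(file, width = wd, height = h)
  }
  on.exit(grDevices::dev.off())
  .draw_composition(a, order, colors, annotations)
  invisible(file)
}
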