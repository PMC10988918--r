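#' Back-gate selection
#'
#' A back-gate inverts the usual gating direction: cells are selected in a
#' low-dimensional embedding (or by a metadata category, or given
#' explicitly), then projected onto a surface-marker scatter to see whether a
#' feature pair separates them — useful to discover which antibodies define a
#' cluster. The selection is represented as a `backgate_selection` object
#' carrying the resolved barcode set and its provenance.
#'
#' @name backgate
NULL

new_backgate_selection <- function(source, detail, barcodes) {
  structure(list(source = source, detail = detail,
                 barcodes = as.character(barcodes)),
            class = "backgate_selection")
}

#' @export
print.backgate_selection <- function(x, ...) {
  cat(sprintf("backgate selection (%s): %d cells\n", x$source,
              length(x$barcodes)))
  invisible(x)
}

#' Select cells by geometry in an embedding
#'
#' Membership uses the same predicate as forward gating
#' ([points_in_geometry()]), applied to the first two embedding dimensions.
#'
#' @param container an [OmicsContainer-class] with the named embedding.
#' @param embedding_name e.g. `"UMAP"`.
#' @param geometry a `gate_geometry` in embedding coordinates.
#' @return a `backgate_selection`.
#' @export
select_in_embedding <- function(container, embedding_name, geometry) {
  if (!embedding_name %in% names(container@embeddings)) {
    stop_fmt("unknown embedding '%s' (available: %s)", embedding_name,
             if (length(container@embeddings))
               paste(names(container@embeddings), collapse = ", ")
             else "none")
  }
  e <- container@embeddings[[embedding_name]]
  if (ncol(e) < 2L) stop_fmt("embedding '%s' has fewer than 2 dimensions",
                             embedding_name)
  inside <- points_in_geometry(e[, 1L], e[, 2L], geometry)
  bcs <- container@barcodes[inside]
  if (!length(bcs)) warn_fmt("embedding selection caught no cells")
  new_backgate_selection("embedding_geometry",
                         list(embedding = embedding_name), bcs)
}

#' Select cells by a metadata category
#'
#' @param container an [OmicsContainer-class].
#' @param column cell_meta column name.
#' @param value category value to select.
#' @return a `backgate_selection`.
#' @export
select_by_metadata <- function(container, column, value) {
  if (!column %in% names(container@cell_meta)) {
    stop_fmt("unknown cell_meta column '%s'", column)
  }
  bcs <- container@barcodes[container@cell_meta[[column]] == value]
  if (!length(bcs)) warn_fmt("no cells with %s == '%s'", column, value)
  new_backgate_selection("metadata_category",
                         list(column = column, value = value), bcs)
}

#' Select explicitly listed cells
#' @param container an [OmicsContainer-class].
#' @param barcodes barcodes to select; must all exist in the container.
#' @return a `backgate_selection`.
#' @export
select_barcodes <- function(container, barcodes) {
  bad <- setdiff(barcodes, container@barcodes)
  if (length(bad)) stop_fmt("unknown barcodes (first: '%s')", bad[1L])
  new_backgate_selection("explicit_barcodes", list(),
                         container@barcodes[container@barcodes %in% barcodes])
}

#' Project a back-gate selection onto a feature pair
#'
#' Returns one row per cell with the two feature values and a `highlighted`
#' flag (cell in selection), mirroring the display convention of gray points
#' with the selected cells drawn dark on top. A summary attribute reports the
#' highlighted count and within/outside medians for each feature.
#'
#' @param container an [OmicsContainer-class].
#' @param selection a `backgate_selection`.
#' @param assay_x,feature_x,assay_y,feature_y the feature pair to project on.
#' @param value_source `"normalized"` (default) or `"raw"`.
#' @return data.frame (barcode, x, y, highlighted) with attribute `summary`.
#' @export
backgate_table <- function(container, selection, assay_x, feature_x,
                           assay_y, feature_y,
                           value_source = c("normalized", "raw")) {
  value_source <- match.arg(value_source)
  stopifnot(inherits(selection, "backgate_selection"))
  vx <- feature_values(container, assay_x, feature_x, source = value_source)
  vy <- feature_values(container, assay_y, feature_y, source = value_source)
  hi <- container@barcodes %in% selection$barcodes
  tab <- data.frame(barcode = container@barcodes, x = as.numeric(vx),
                    y = as.numeric(vy), highlighted = hi,
                    stringsAsFactors = FALSE)
  med <- function(v) if (length(v)) median(v) else NA_real_
  attr(tab, "summary") <- list(
    n_highlighted = sum(hi),
    feature_x = feature_x, feature_y = feature_y,
    median_x_in = med(tab$x[hi]), median_x_out = med(tab$x[!hi]),
    median_y_in = med(tab$y[hi]), median_y_out = med(tab$y[!hi]))
  tab
}

#' 2-D density histogram over a point cloud
#'
#' A binned density layer for the contour underlay of feature scatters: a
#' 2-D histogram over the data's bounding box. Counts are conserved exactly
#' (the grid sums to the number of points). `smooth = TRUE` applies one pass
#' of bilinear smoothing for display (the smoothed grid still sums to n).
#'
#' @param values_x,values_y point coordinates.
#' @param bins grid resolution per axis (default 64).
#' @param smooth apply bilinear smoothing (default FALSE).
#' @return bins x bins numeric matrix; attributes `xbreaks`, `ybreaks`.
#' @export
density_grid <- function(values_x, values_y, bins = 64L, smooth = FALSE) {
  stopifnot(length(values_x) == length(values_y), length(values_x) > 0,
            bins >= 1L)
  rx <- range(values_x); ry <- range(values_y)
  if (rx[1] == rx[2]) rx <- rx + c(-0.5, 0.5)
  if (ry[1] == ry[2]) ry <- ry + c(-0.5, 0.5)
  xb <- seq(rx[1], rx[2], length.out = bins + 1L)
  yb <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(values_x, xb, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(values_y, yb, rightmost.closed = TRUE), 1L), bins)
  g <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  g[] <- as.numeric(tab)
  if (smooth && bins >= 3L) {
    k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
    sm <- matrix(0, bins, bins)
    for (di in -1:1) for (dj in -1:1) {
      w <- k[di + 2L, dj + 2L]
      src_i <- pmin(pmax(seq_len(bins) + di, 1L), bins)
      src_j <- pmin(pmax(seq_len(bins) + dj, 1L), bins)
      sm <- sm + w * g[src_i, src_j, drop = FALSE]
    }
    sm <- sm * (sum(g) / sum(sm))   # renormalize to conserve total count
    g <- sm
  }
  attr(g, "xbreaks") <- xb
  attr(g, "ybreaks") <- yb
  g
}
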