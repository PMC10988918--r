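#' Multi-assay single-cell container
#'
#' `OmicsContainer` holds multimodal single-cell data keyed by shared cell
#' barcodes: one or more assays (cells x features count matrices, each with an
#' optional normalized companion matrix), any number of low-dimensional
#' embeddings (cells x d coordinates computed upstream), and a per-cell
#' metadata table. Cell barcodes are the primary key everywhere; positional
#' indices are never part of the public contract. Matrices are stored
#' cells-as-rows; raw counts are sparse (`dgCMatrix`), normalized matrices
#' dense.
#'
#' Gating requires an `ADT` assay. A container lacking one is flagged
#' `gateable = FALSE` and gating operations refuse it.
#'
#' @slot barcodes character vector of unique cell barcodes (row key).
#' @slot assays named list; each element is a list with `features` (character),
#'   `raw` (cells x features `dgCMatrix`, non-negative), and `normalized`
#'   (dense numeric matrix or `NULL`).
#' @slot embeddings named list of cells x d numeric matrices.
#' @slot cell_meta `data.frame` of per-cell annotations, rownames = barcodes.
#' @slot norm_record list recording how the ADT assay was normalized
#'   (`method`, `margin`, `variant`, `pseudocount`); empty until
#'   [normalize_adt()] runs or an external matrix is registered.
#' @slot gateable logical; `TRUE` iff an ADT assay is present.
#'
#' @seealso [omics_container()], [read_10x_mtx()], [read_container()]
#' @export
setClass("OmicsContainer", representation(
  barcodes = "character",
  assays = "list",
  embeddings = "list",
  cell_meta = "data.frame",
  norm_record = "list",
  gateable = "logical"
))

setValidity("OmicsContainer", function(object) {
  n <- length(object@barcodes)
  if (n == 0L) return("container must hold at least one cell")
  if (anyDuplicated(object@barcodes)) {
    dup <- object@barcodes[duplicated(object@barcodes)][1L]
    return(sprintf("duplicate cell barcode: '%s'", dup))
  }
  for (nm in names(object@assays)) {
    a <- object@assays[[nm]]
    if (!all(c("features", "raw") %in% names(a))) {
      return(sprintf("assay '%s' missing features/raw", nm))
    }
    if (anyDuplicated(a$features)) {
      return(sprintf("assay '%s' has duplicate feature names", nm))
    }
    if (nrow(a$raw) != n) {
      return(sprintf("assay '%s' raw matrix has %d rows, expected %d cells",
                     nm, nrow(a$raw), n))
    }
    if (ncol(a$raw) != length(a$features)) {
      return(sprintf("assay '%s' raw matrix has %d columns for %d features",
                     nm, ncol(a$raw), length(a$features)))
    }
    if (min(a$raw) < 0) return(sprintf("assay '%s' has negative raw counts", nm))
    if (!is.null(a$normalized) &&
        (nrow(a$normalized) != n || ncol(a$normalized) != length(a$features))) {
      return(sprintf("assay '%s' normalized matrix shape mismatch", nm))
    }
  }
  for (nm in names(object@embeddings)) {
    if (nrow(object@embeddings[[nm]]) != n) {
      return(sprintf("embedding '%s' has %d rows, expected %d",
                     nm, nrow(object@embeddings[[nm]]), n))
    }
  }
  if (nrow(object@cell_meta) > 0L && nrow(object@cell_meta) != n) {
    return("cell_meta row count differs from number of barcodes")
  }
  TRUE
})

#' Construct an OmicsContainer
#'
#' @param barcodes character vector of unique cell barcodes.
#' @param assays named list of assays; each element either a bare cells x
#'   features matrix (taken as raw counts) or a list with `raw`, optional
#'   `normalized`, optional `features` (defaults to matrix column names).
#' @param embeddings named list of cells x d numeric matrices.
#' @param cell_meta data.frame of per-cell annotations (one row per barcode).
#' @param norm_record list describing ADT normalization provenance.
#' @return A validated [OmicsContainer-class] object.
#' @examples
#' adt <- matrix(rpois(6, 5), 3, 2, dimnames = list(NULL, c("CD3", "CD19")))
#' oc <- omics_container(paste0("cell", 1:3), assays = list(ADT = adt))
#' n_cells(oc)
#' @export
omics_container <- function(barcodes, assays = list(), embeddings = list(),
                            cell_meta = NULL, norm_record = list()) {
  barcodes <- as.character(barcodes)
  assays <- lapply(assays, function(a) {
    if (is.matrix(a) || methods::is(a, "Matrix")) a <- list(raw = a)
    if (is.null(a$features)) {
      a$features <- colnames(a$raw)
      if (is.null(a$features)) {
        stop_fmt("assay matrix needs column names or an explicit `features` vector")
      }
    }
    a$raw <- methods::as(methods::as(Matrix::Matrix(a$raw, sparse = TRUE),
                                     "CsparseMatrix"), "generalMatrix")
    # shape mismatches are reported by the validity method, not masked here
    if (identical(dim(a$raw), c(length(barcodes), length(a$features)))) {
      dimnames(a$raw) <- list(barcodes, a$features)
    }
    if (!is.null(a$normalized)) {
      a$normalized <- as.matrix(a$normalized)
      if (identical(dim(a$normalized),
                    c(length(barcodes), length(a$features)))) {
        dimnames(a$normalized) <- list(barcodes, a$features)
      }
    }
    a[c("features", "raw", "normalized")]
  })
  embeddings <- lapply(embeddings, function(e) {
    e <- as.matrix(e)
    if (nrow(e) == length(barcodes)) rownames(e) <- barcodes
    e
  })
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = barcodes)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) == length(barcodes)) rownames(cell_meta) <- barcodes
  }
  methods::new("OmicsContainer",
    barcodes = barcodes, assays = assays, embeddings = embeddings,
    cell_meta = cell_meta, norm_record = norm_record,
    gateable = "ADT" %in% names(assays))
}

#' Number of cells in a container
#' @param x an [OmicsContainer-class].
#' @return integer cell count.
#' @export
n_cells <- function(x) length(x@barcodes)

#' Assay names of a container
#' @param x an [OmicsContainer-class].
#' @return character vector.
#' @export
assay_names <- function(x) names(x@assays)

#' @export
setMethod("show", "OmicsContainer", function(object) {
  cat(sprintf("OmicsContainer: %d cells\n", n_cells(object)))
  for (nm in names(object@assays)) {
    a <- object@assays[[nm]]
    cat(sprintf("  assay %s: %d features%s\n", nm, length(a$features),
                if (is.null(a$normalized)) "" else " (normalized)"))
  }
  if (length(object@embeddings)) {
    cat("  embeddings:", paste(names(object@embeddings), collapse = ", "), "\n")
  }
  if (ncol(object@cell_meta)) {
    cat("  cell_meta:", paste(names(object@cell_meta), collapse = ", "), "\n")
  }
  if (!object@gateable) cat("  [not gateable: no ADT assay]\n")
})

resolve_feature <- function(container, assay, feature) {
  if (!assay %in% names(container@assays)) {
    stop_fmt("assay '%s' not found (available: %s)", assay,
             paste(names(container@assays), collapse = ", "))
  }
  a <- container@assays[[assay]]
  if (!feature %in% a$features) {
    stop_fmt("feature '%s' not found in assay '%s'", feature, assay)
  }
  invisible(TRUE)
}

#' Extract one feature's values for a set of cells
#'
#' By default ADT values are read from the normalized slot, matching the
#' workflow's requirement that gating operates on normalized antibody counts;
#' pass `source = "raw"` explicitly to gate on raw counts.
#'
#' @param container an [OmicsContainer-class].
#' @param assay,feature names resolving into the container.
#' @param barcodes cells to extract (default: all), in the given order.
#' @param source `"normalized"` or `"raw"`.
#' @return named numeric vector keyed by barcode.
#' @export
feature_values <- function(container, assay, feature,
                           barcodes = container@barcodes,
                           source = c("normalized", "raw")) {
  source <- match.arg(source)
  resolve_feature(container, assay, feature)
  a <- container@assays[[assay]]
  bad <- setdiff(barcodes, container@barcodes)
  if (length(bad)) stop_fmt("unknown barcodes (first: '%s')", bad[1L])
  if (source == "normalized") {
    if (is.null(a$normalized)) {
      stop_fmt(
        "assay '%s' has no normalized matrix; run normalize_adt() or request source = \"raw\"",
        assay)
    }
    m <- a$normalized
  } else {
    m <- a$raw
  }
  v <- as.numeric(m[barcodes, feature])
  names(v) <- barcodes
  v
}

#' Subset a container to a set of barcodes
#'
#' All assays, embeddings and metadata are subset consistently; barcode order
#' within the container is preserved (the subset keeps container order, not
#' the order of `barcodes`).
#'
#' @param container an [OmicsContainer-class].
#' @param barcodes barcodes to keep; must all exist.
#' @return a smaller [OmicsContainer-class].
#' @export
subset_cells <- function(container, barcodes) {
  bad <- setdiff(barcodes, container@barcodes)
  if (length(bad)) stop_fmt("unknown barcodes (first: '%s')", bad[1L])
  keep <- container@barcodes[container@barcodes %in% barcodes]
  if (!length(keep)) stop_fmt("subset would leave zero cells")
  assays <- lapply(container@assays, function(a) {
    list(features = a$features,
         raw = a$raw[keep, , drop = FALSE],
         normalized = if (is.null(a$normalized)) NULL else
           a$normalized[keep, , drop = FALSE])
  })
  embeddings <- lapply(container@embeddings,
                       function(e) e[keep, , drop = FALSE])
  meta <- container@cell_meta[keep, , drop = FALSE]
  out <- omics_container(keep, assays, embeddings, meta,
                         norm_record = container@norm_record)
  out
}

# Cheap structural fingerprint used in chain metadata and audit files so a
# replay can detect it is running against a different container.
container_fingerprint <- function(container) {
  tot <- vapply(container@assays, function(a) sum(a$raw), numeric(1))
  sprintf("cells=%d;assays=%s;counts=%s;first=%s;last=%s",
          n_cells(container),
          paste(sprintf("%s:%d", names(container@assays),
                        vapply(container@assays, function(a)
                          length(a$features), integer(1))), collapse = ","),
          paste(fmt_full(tot), collapse = ","),
          container@barcodes[1L],
          container@barcodes[n_cells(container)])
}
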