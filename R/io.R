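#' Read a 10x-style MTX triplet directory
#'
#' Reads `matrix.mtx[.gz]`, `barcodes.tsv[.gz]` and `features.tsv[.gz]` from
#' a directory. The features file must carry a feature-type column (the
#' standard third column): rows typed `"Gene Expression"` populate the `RNA`
#' assay and rows typed `"Antibody Capture"` the `ADT` assay. Counts and
#' barcode order are preserved exactly; the MTX file's 1-based coordinate
#' convention and features-as-rows orientation are handled on read.
#'
#' @param path directory containing the triplet.
#' @param feature_name_col which features.tsv column to use as the feature
#'   name (2 = gene symbol, the 10x default; 1 = id).
#' @return an [OmicsContainer-class] with assays `RNA` and/or `ADT`.
#' @export
read_10x_mtx <- function(path, feature_name_col = 2L) {
  find_member <- function(base) {
    for (f in file.path(path, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop_fmt("10x directory '%s' is missing required file '%s[.gz]'",
             path, base)
  }
  mtx_f <- find_member("matrix.mtx")
  bc_f <- find_member("barcodes.tsv")
  ft_f <- find_member("features.tsv")

  m <- Matrix::readMM(mtx_f)                     # features x cells
  barcodes <- readLines(bc_f)
  feats <- read.delim(ft_f, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(feats) < 3L) {
    stop_fmt("features file '%s' lacks a feature-type column (need >= 3 columns)",
             ft_f)
  }
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m)) {
    stop_fmt("matrix is %d x %d but features/barcodes have %d/%d rows",
             nrow(m), ncol(m), nrow(feats), length(barcodes))
  }
  if (anyDuplicated(barcodes)) {
    stop_fmt("duplicate barcode in '%s': '%s'", bc_f,
             barcodes[duplicated(barcodes)][1L])
  }
  m <- Matrix::t(m)                              # cells x features
  type <- feats[[3L]]
  fname <- as.character(feats[[feature_name_col]])
  assays <- list()
  type_map <- c("Gene Expression" = "RNA", "Antibody Capture" = "ADT")
  for (tt in names(type_map)) {
    idx <- which(type == tt)
    if (!length(idx)) next
    sub <- m[, idx, drop = FALSE]
    assays[[type_map[[tt]]]] <- list(raw = sub, features = fname[idx])
  }
  if (!length(assays)) {
    stop_fmt("no 'Gene Expression' or 'Antibody Capture' rows in '%s'", ft_f)
  }
  oc <- omics_container(barcodes, assays)
  if (!oc@gateable) {
    warn_fmt("no 'Antibody Capture' features found: container is not gateable")
  }
  oc
}

#' Read a cells-x-features CSV matrix as one assay
#'
#' Header row = feature names, first column = cell barcodes.
#'
#' @param path CSV file.
#' @param assay assay name to store the matrix under (default `"ADT"`).
#' @param normalized if `TRUE`, the values are stored in the normalized slot
#'   (raw is zero-filled) and `norm_record` is marked `external`.
#' @return an [OmicsContainer-class].
#' @export
read_csv_matrix <- function(path, assay = "ADT", normalized = FALSE) {
  d <- read.delim(path, sep = ",", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  barcodes <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  mode(m) <- "double"
  a <- if (normalized) {
    list(raw = matrix(0, nrow(m), ncol(m), dimnames = dimnames(m)),
         normalized = m, features = colnames(m))
  } else list(raw = m, features = colnames(m))
  rec <- if (normalized && assay == "ADT") list(method = "external") else list()
  omics_container(barcodes, setNames(list(a), assay), norm_record = rec)
}

container_bundle_version <- "1.0"

#' Write a container to a plain-text bundle
#'
#' Serializes an [OmicsContainer-class] to a directory: a JSON manifest
#' (barcodes, feature names, embeddings, metadata, normalization record), one
#' MatrixMarket file per assay's raw counts, and full-precision TSV for each
#' normalized matrix. The round trip through [read_container()] is lossless:
#' raw counts bit-exact, normalized values to full double precision.
#'
#' @param container an [OmicsContainer-class].
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_container <- function(container, path) {
  stopifnot(methods::is(container, "OmicsContainer"))
  methods::validObject(container)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_fmt("cannot create bundle directory '%s'", path)
  manifest <- list(
    schema_version = container_bundle_version,
    barcodes = container@barcodes,
    assays = lapply(container@assays, function(a)
      list(features = a$features, has_normalized = !is.null(a$normalized))),
    embeddings = lapply(container@embeddings, function(e)
      list(d = ncol(e))),
    cell_meta_columns = names(container@cell_meta),
    norm_record = container@norm_record
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(container@assays)) {
    a <- container@assays[[nm]]
    Matrix::writeMM(a$raw, file.path(path, sprintf("assay_%s_raw.mtx", nm)))
    if (!is.null(a$normalized)) {
      write_full_precision_tsv(a$normalized,
        file.path(path, sprintf("assay_%s_normalized.tsv", nm)))
    }
  }
  for (nm in names(container@embeddings)) {
    write_full_precision_tsv(container@embeddings[[nm]],
      file.path(path, sprintf("embedding_%s.tsv", nm)))
  }
  if (ncol(container@cell_meta)) {
    write.table(container@cell_meta, file.path(path, "cell_meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

write_full_precision_tsv <- function(m, path) {
  txt <- apply(m, 1L, function(r) paste(fmt_full(r), collapse = "\t"))
  writeLines(txt, path)
}

read_full_precision_tsv <- function(path, n_col) {
  lines <- readLines(path)
  m <- matrix(as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE))),
              nrow = length(lines), ncol = n_col, byrow = TRUE)
  m
}

#' Read a container bundle written by [write_container()]
#'
#' A bundle whose assays include no ADT-like modality is returned with
#' `gateable = FALSE` and a warning: such a container can feed QC but not the
#' gating workflow.
#'
#' @param path bundle directory.
#' @return an [OmicsContainer-class].
#' @export
read_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop_fmt("'%s' is not a container bundle (no manifest.json)", path)
  }
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                       error = function(e)
                         stop_fmt("corrupt manifest in '%s': %s", path,
                                  conditionMessage(e)))
  if (!identical(as.character(manifest$schema_version),
                 container_bundle_version)) {
    stop_fmt("container bundle schema version mismatch: found '%s', expected '%s'",
             manifest$schema_version, container_bundle_version)
  }
  barcodes <- manifest$barcodes
  n <- length(barcodes)
  assay_meta <- manifest$assays
  assays <- list()
  for (nm in names(assay_meta)) {
    feats <- assay_meta[[nm]]$features
    raw <- Matrix::readMM(file.path(path, sprintf("assay_%s_raw.mtx", nm)))
    a <- list(raw = raw, features = feats)
    if (isTRUE(assay_meta[[nm]]$has_normalized)) {
      a$normalized <- read_full_precision_tsv(
        file.path(path, sprintf("assay_%s_normalized.tsv", nm)),
        length(feats))
    }
    assays[[nm]] <- a
  }
  # modality aliasing: an assay stored as "Antibody Capture" maps to ADT
  if (!"ADT" %in% names(assays) && "Antibody Capture" %in% names(assays)) {
    names(assays)[names(assays) == "Antibody Capture"] <- "ADT"
  }
  embeddings <- list()
  for (nm in names(manifest$embeddings)) {
    embeddings[[nm]] <- read_full_precision_tsv(
      file.path(path, sprintf("embedding_%s.tsv", nm)),
      manifest$embeddings[[nm]]$d)
  }
  meta <- NULL
  if (length(manifest$cell_meta_columns)) {
    meta <- read.delim(file.path(path, "cell_meta.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
  }
  nr <- manifest$norm_record
  oc <- omics_container(barcodes, assays, embeddings, meta,
                        norm_record = if (is.null(nr)) list() else as.list(nr))
  if (!oc@gateable) {
    warn_fmt("bundle '%s' has no ADT assay: container flagged not gateable", path)
  }
  oc
}

#' Randomly down-sample a container to n cells
#'
#' Uniform sampling of barcodes without replacement; all assays, embeddings
#' and metadata are subset consistently. The same seed always yields the same
#' barcode set. Down-sampling to a workable size (the demonstration dataset
#' was reduced to 10,000 cells this way) keeps scatter plots readable without
#' biasing population proportions.
#'
#' @param container an [OmicsContainer-class].
#' @param n number of cells to keep, `0 < n <= n_cells(container)`.
#' @param seed integer seed for the draw.
#' @return a down-sampled [OmicsContainer-class].
#' @export
downsample <- function(container, n, seed) {
  nc <- n_cells(container)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_fmt("`n` must be a positive integer")
  }
  if (n > nc) stop_fmt("cannot down-sample to %d cells from %d", n, nc)
  keep <- with_seed(seed, sample(container@barcodes, size = n))
  subset_cells(container, keep)
}

#' Write a barcode list to a text file
#'
#' One barcode per line, newline-terminated, order preserved. A `.gz`
#' extension gzip-compresses the output.
#'
#' @param barcodes character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  if (!length(barcodes)) warn_fmt("writing an empty barcode list to '%s'", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.character(barcodes), con)
  invisible(path)
}

#' Read a barcode list written by [write_barcodes()]
#' @param path text file, optionally gzipped.
#' @return character vector.
#' @export
read_barcodes <- function(path) readLines(path)
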