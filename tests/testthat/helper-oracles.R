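# Independent oracles and in-code fixtures shared across the suite.

# Winding-number membership oracle: sums the signed angles subtended by each
# polygon edge at the point; |total| > pi means the point is enclosed. For
# simple polygons this is equivalent to (and independent of) the even-odd
# ray-casting rule used by the implementation.
oracle_polygon_inside <- function(x, y, px, py) {
  n <- length(px)
  total <- numeric(length(x))
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    ax <- px[k] - x; ay <- py[k] - y
    bx <- px[j] - x; by <- py[j] - y
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(total) > pi
}

# Minimum distance from each point to any polygon edge (for excluding
# numerically edge-adjacent points from oracle comparisons).
oracle_edge_distance <- function(x, y, px, py) {
  n <- length(px)
  dmin <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    ex <- px[j] - px[k]; ey <- py[j] - py[k]
    len2 <- ex^2 + ey^2
    t <- pmin(pmax(((x - px[k]) * ex + (y - py[k]) * ey) / len2, 0), 1)
    dx <- x - (px[k] + t * ex); dy <- y - (py[k] + t * ey)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

# Random simple polygon: distinct sorted angles around a center with random
# radii. Each edge then stays inside its own angular wedge provided every
# consecutive angular gap is below pi, so no two non-adjacent edges can
# cross: the polygon is simple and the even-odd and winding rules must agree
# everywhere off the boundary.
random_star_polygon <- function(n_vertices) {
  repeat {
    ang <- sort(runif(n_vertices, 0, 2 * pi))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    if (min(gaps) > 1e-3 && max(gaps) < pi - 1e-2) break
  }
  r <- runif(n_vertices, 0.5, 2)
  cx <- runif(1, -1, 1); cy <- runif(1, -1, 1)
  list(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Five-cell toy container with exact normalized ADT values, for gate
# enumeration by hand.
toy_container <- function() {
  vals <- cbind(CD3 = c(0.1, 2.0, 2.1, 0.2, 1.9),
                CD4 = c(0.0, 1.8, 0.1, 0.0, 1.7))
  omics_container(
    paste0("c", 1:5),
    assays = list(ADT = list(
      raw = matrix(0, 5, 2, dimnames = list(NULL, colnames(vals))),
      normalized = vals,
      features = colnames(vals))),
    norm_record = list(method = "external"))
}

# Write a tiny 10x MTX triplet: 3 cells x (2 genes + 2 antibodies).
# `explicit_zero` adds a stored zero entry to the sparse file.
write_10x_fixture <- function(dir, explicit_zero = FALSE,
                              duplicate_barcode = FALSE,
                              drop_type_column = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # counts, features x cells: rows GeneA GeneB AbCD3 AbCD19
  entries <- rbind(
    c(1, 1, 5), c(1, 3, 2),
    c(2, 2, 7),
    c(3, 1, 10), c(3, 2, 4), c(3, 3, 1),
    c(4, 2, 3))
  if (explicit_zero) entries <- rbind(entries, c(2, 1, 0))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("4 3 %d", nrow(entries)),
               apply(entries, 1, paste, collapse = " ")),
             file.path(dir, "matrix.mtx"))
  bcs <- c("AAA-1", "AAC-1", if (duplicate_barcode) "AAA-1" else "AAG-1")
  writeLines(bcs, file.path(dir, "barcodes.tsv"))
  feats <- c("ENSG01\tGeneA\tGene Expression",
             "ENSG02\tGeneB\tGene Expression",
             "AB01\tCD3\tAntibody Capture",
             "AB02\tCD19\tAntibody Capture")
  if (drop_type_column) feats <- sub("\t[^\t]+$", "", feats)
  writeLines(feats, file.path(dir, "features.tsv"))
  invisible(dir)
}

# Small normalized PBMC preset container cached per test run.
small_pbmc <- local({
  cache <- NULL
  function(n_cells = 2000, seed = 7L) {
    if (is.null(cache)) {
      sim <- generate_synthetic(pbmc_preset(n_cells = n_cells, seed = seed))
      sim$container <- normalize_adt(sim$container)
      cache <<- sim
    }
    cache
  }
})

# Independent Tukey-Kramer adjusted p: studentized range on the observed
# pairwise difference with the pooled within-group mean square.
oracle_tukey_padj <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  df <- length(y) - k
  mse <- sum((y - mi[g])^2) / df
  combs <- utils::combn(levels(g), 2)
  apply(combs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    q <- abs(mi[pr[2]] - mi[pr[1]]) / se
    stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  })
}
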