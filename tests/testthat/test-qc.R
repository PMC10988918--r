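test_that("QC metrics are computed from raw counts with absent assays omitted", {
  adt <- rbind(c(0, 2, 0, 7), c(0, 0, 0, 0))
  colnames(adt) <- paste0("ab", 1:4)
  rna <- rbind(c(3, 0, 1), c(0, 0, 0))
  colnames(rna) <- paste0("g", 1:3)
  oc <- omics_container(c("c1", "c2"),
                        assays = list(RNA = rna, ADT = adt),
                        cell_meta = data.frame(donor = c("d1", "d2")))
  qc <- compute_qc(oc)
  expect_equal(qc$n_antibodies_detected, c(2L, 0L))
  expect_equal(qc$total_adt_counts, c(9, 0))
  expect_equal(qc$n_genes_detected, c(2L, 0L))
  expect_equal(qc$total_rna_counts, c(4, 0))
  expect_equal(qc$donor, c("d1", "d2"))

  adt_only <- omics_container(c("c1", "c2"), assays = list(ADT = adt))
  expect_false("total_rna_counts" %in% names(compute_qc(adt_only)))
})

test_that("QC metrics are invariant to normalization", {
  sim <- small_pbmc()
  raw_qc <- compute_qc(generate_synthetic(pbmc_preset(2000, 7))$container)
  norm_qc <- compute_qc(sim$container)
  expect_equal(raw_qc$n_antibodies_detected, norm_qc$n_antibodies_detected)
  expect_equal(raw_qc$total_adt_counts, norm_qc$total_adt_counts)
})

test_that("group_compare matches an independent Tukey-Kramer computation", {
  set.seed(17)
  y <- c(rnorm(12, 0), rnorm(9, 0.8), rnorm(15, 0.3), rnorm(10, -0.5))
  g <- rep(c("a", "b", "c", "d"), c(12, 9, 15, 10))
  gc <- group_compare(data.frame(m = y, g = g), "m", "g")
  expect_equal(nrow(gc$pairs), 6L)       # k(k-1)/2 for k = 4
  want <- oracle_tukey_padj(y, g)   # named by unordered pair, combn order
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  names(want) <- apply(utils::combn(sort(unique(g)), 2), 2,
                       function(p) key(p[1], p[2]))
  got <- setNames(gc$pairs$padj, key(gc$pairs$group_i, gc$pairs$group_j))
  expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-10)
})

test_that("two-group Tukey padj equals the ANOVA p-value", {
  set.seed(19)
  for (i in 1:5) {
    y <- rnorm(40)
    g <- rep(c("a", "b"), 20)
    gc <- group_compare(data.frame(m = y, g = g), "m", "g")
    expect_equal(gc$pairs$padj[1], gc$anova$p, tolerance = 1e-6)
  }
})

test_that("degenerate equal-group case gives F = 0 and padj = 1", {
  # three groups with identical means and identical within-group spread
  y <- rep(c(1, 3), 3)
  g <- rep(c("a", "b", "c"), each = 2)
  gc <- group_compare(data.frame(m = y, g = g), "m", "g")
  expect_equal(gc$anova$F, 0)
  expect_equal(gc$pairs$padj, rep(1, 3))
})

test_that("small groups are dropped and too-few groups error", {
  qc <- data.frame(m = c(1, 2, 3, 4, 5), g = c("a", "a", "b", "b", "c"))
  expect_warning(gc <- group_compare(qc, "m", "g"), "c")
  expect_equal(sort(gc$groups$group), c("a", "b"))
  expect_error(suppressWarnings(
    group_compare(data.frame(m = 1:3, g = c("a", "a", "b")), "m", "g")),
    "at least 2 groups")
  expect_error(group_compare(qc, "nope", "g"), "nope")
})

test_that("a 3-SD mean shift is detected in nearly every replicate", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(600 + s)
    y <- c(rnorm(100, 0, 1), rnorm(100, 3, 1))
    g <- rep(c("a", "b"), each = 100)
    gc <- group_compare(data.frame(m = y, g = g), "m", "g")
    if (gc$pairs$padj[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.99)
})

test_that("co-expression quadrants are exhaustive and recover the DP monocytes", {
  sim <- small_pbmc()
  oc <- sim$container
  tab <- coexpression_table(oc, "ADT", "CD14", "ADT", "CD16",
                            thresholds = c(-Inf, -Inf))
  expect_true(all(tab$quadrant == "double_positive"))

  thr <- suggest_thresholds(oc, features = c("CD14", "CD16"))
  tab <- coexpression_table(oc, "ADT", "CD14", "ADT", "CD16",
                            thresholds = unname(thr))
  expect_equal(sum(table(tab$quadrant)), n_cells(oc))
  dp <- sim$truth$barcode[sim$truth$population == "cd14_cd16_mono"]
  frac <- mean(tab$quadrant[tab$barcode %in% dp] == "double_positive")
  expect_gte(frac, 0.9)
})
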