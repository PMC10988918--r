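test_that("clr matches the hand-computed log1p-centered transform", {
  # log1p of (0, 3, 15) is (0, 2*log2, 4*log2); mean 2*log2
  out <- clr_normalize(matrix(c(0, 3, 15), 1, 3), margin = "within_cell")
  expect_equal(as.numeric(out), c(-2 * log(2), 0, 2 * log(2)),
               tolerance = 1e-12)
  # pure log-ratio with pseudocount 0.5
  lg <- log(c(0, 3, 15) + 0.5)
  out2 <- clr_normalize(matrix(c(0, 3, 15), 1, 3), margin = "within_cell",
                        variant = "pure_log_ratio", pseudocount = 0.5)
  expect_equal(as.numeric(out2), lg - mean(lg), tolerance = 1e-12)
})

test_that("clr centering, constants and degenerate vectors behave", {
  expect_equal(as.numeric(clr_normalize(matrix(5, 1, 3),
                                        margin = "within_cell")),
               c(0, 0, 0))
  set.seed(11)
  m <- matrix(rpois(200, 4), 20, 10)
  for (margin in c("within_cell", "across_cells")) {
    for (variant in c("log1p_centered", "pure_log_ratio")) {
      out <- clr_normalize(m, margin = margin, variant = variant)
      mu <- if (margin == "within_cell") rowMeans(out) else colMeans(out)
      expect_lt(max(abs(mu)), 1e-12)
    }
  }
  # all-zero margin vector maps to zeros, not NaN
  z <- m; z[, 1] <- 0
  out <- clr_normalize(z, margin = "across_cells")
  expect_equal(out[, 1], rep(0, 20))
  z2 <- m; z2[1, ] <- 0
  out2 <- clr_normalize(z2, margin = "within_cell")
  expect_equal(unname(out2[1, ]), rep(0, 10))
  expect_error(clr_normalize(matrix(-1, 1, 2)), "non-negative")
  expect_error(clr_normalize(m, pseudocount = 0,
                             variant = "pure_log_ratio"), "pseudocount")
})

test_that("clr is monotone and permutation-equivariant within a margin vector", {
  set.seed(22)
  for (i in 1:20) {
    x <- rpois(15, 10)
    y <- as.numeric(clr_normalize(matrix(x, 1), margin = "within_cell"))
    expect_true(all(diff(y[order(x)]) >= 0))
    p <- sample(15)
    yp <- as.numeric(clr_normalize(matrix(x[p], 1), margin = "within_cell"))
    expect_equal(yp, y[p])
  }
})

test_that("RNA log-normalization follows the library-size formula", {
  expect_equal(as.numeric(log_normalize_rna(matrix(10, 1, 1),
                                            scale_factor = 10)),
               log(11))
  expect_warning(out <- log_normalize_rna(rbind(c(0, 0), c(2, 3)),
                                          scale_factor = 100),
                 "zero total")
  expect_equal(out[1, ], c(0, 0))
  # per nonzero cell, sum(exp(y) - 1) recovers the scale factor
  set.seed(3)
  m <- matrix(rpois(50, 5) + 1, 5, 10)
  y <- log_normalize_rna(m, scale_factor = 1e4)
  expect_equal(rowSums(expm1(y)), rep(1e4, 5))
})

test_that("normalize_adt fills the slot and records provenance", {
  sim <- generate_synthetic(pbmc_preset(n_cells = 200, seed = 5))
  oc <- normalize_adt(sim$container, margin = "within_cell")
  expect_false(is.null(oc@assays$ADT$normalized))
  expect_equal(oc@norm_record,
               list(method = "clr", margin = "within_cell",
                    variant = "log1p_centered", pseudocount = 1))
  expect_error(normalize_adt(sim$container, method = "external"),
               "pre-filled")
  rna_only <- omics_container("c1", assays = list(
    RNA = matrix(1, 1, 1, dimnames = list(NULL, "g"))))
  expect_error(normalize_adt(rna_only), "no ADT assay")
})
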