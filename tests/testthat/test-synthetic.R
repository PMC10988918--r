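test_that("generation is fully reproducible under a fixed seed", {
  spec <- pbmc_preset(n_cells = 500, seed = 123)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(as.matrix(a$container@assays$ADT$raw),
                   as.matrix(b$container@assays$ADT$raw))
  expect_identical(as.matrix(a$container@assays$RNA$raw),
                   as.matrix(b$container@assays$RNA$raw))
  expect_identical(a$container@embeddings$UMAP, b$container@embeddings$UMAP)
  expect_identical(a$truth, b$truth)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(55)
  before <- .Random.seed
  invisible(generate_synthetic(pbmc_preset(n_cells = 100, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("population proportions land inside the binomial 99% CI", {
  n <- 5000
  sim <- generate_synthetic(pbmc_preset(n_cells = n, seed = 77))
  spec <- pbmc_preset(n_cells = n, seed = 77)
  props <- vapply(spec$populations, `[[`, numeric(1), "proportion")
  names(props) <- vapply(spec$populations, `[[`, "", "name")
  counts <- table(factor(sim$truth$population, levels = names(props)))
  for (p in names(props)) {
    se <- sqrt(n * props[[p]] * (1 - props[[p]]))
    expect_lt(abs(counts[[p]] - n * props[[p]]), 2.576 * se + 1)
  }
})

test_that("per-population ADT means match the negative-binomial expectation", {
  sim <- generate_synthetic(pbmc_preset(n_cells = 10000, seed = 31))
  raw <- as.matrix(sim$container@assays$ADT$raw)
  # positive markers have NB mean exp(5), negatives exp(1)
  for (chk in list(c("cd4_t", "CD3", 5), c("cd4_t", "CD4", 5),
                   c("b", "CD19", 5), c("cd4_t", "CD19", 1),
                   c("nk", "CD56", 5))) {
    cells <- sim$truth$barcode[sim$truth$population == chk[1]]
    m <- mean(raw[cells, chk[2]])
    expect_lt(abs(m - exp(as.numeric(chk[3]))) / exp(as.numeric(chk[3])),
              0.05)
  }
})

test_that("spec validation rejects broken inputs", {
  spec <- pbmc_preset(100, 1)
  bad <- spec$populations
  bad[[1]]$proportion <- 0.5
  expect_error(synthetic_spec(bad, 100, pbmc_panel_features()),
               "sum to")
  bad2 <- spec$populations
  bad2[[1]]$adt_log_means <- bad2[[1]]$adt_log_means[-1]
  expect_error(synthetic_spec(bad2, 100, pbmc_panel_features()),
               "lacks adt_log_means")
  expect_error(pbmc_preset(100, 1, donor_block_dropout = c(0, 2)),
               "\\[0, 1\\]")
})

test_that("CLR-normalized CD3 separates T cells from the rest bimodally", {
  sim <- small_pbmc()
  oc <- sim$container
  v <- oc@assays$ADT$normalized[, "CD3"]
  km <- kmeans(v, centers = matrix(quantile(v, c(0.05, 0.95)), 2, 1))
  hi <- which.max(km$centers)
  is_t <- sim$truth$population %in% c("cd4_t", "cd8_t")
  agree <- mean((km$cluster == hi) == is_t)
  expect_gte(agree, 0.99)
  # the two modes are far apart relative to their spreads
  expect_gt(abs(diff(km$centers)),
            3 * max(tapply(v, km$cluster, sd)))
})

test_that("the preset generates 10,000 cells within the performance budget", {
  t0 <- Sys.time()
  sim <- generate_synthetic(pbmc_preset(n_cells = 10000, seed = 2))
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_equal(n_cells(sim$container), 10000L)
  expect_lt(elapsed, 30)
})

test_that("recovery_eval scores perfect and empty outputs correctly", {
  sim <- generate_synthetic(pbmc_preset(n_cells = 300, seed = 9))
  oc <- normalize_adt(sim$container)
  truth_b <- sim$truth$barcode[sim$truth$population == "b"]
  chain <- gate_chain(oc)
  # a fake perfect gate: subset to the truth set via explicit membership
  g <- apply_gate(oc, "perfect", "ADT", "CD19", "ADT", "CD3",
                  rectangle_gate(-100, 100, -100, 100))
  g@output_barcodes <- oc@barcodes[oc@barcodes %in% truth_b]
  g@output_count <- length(g@output_barcodes)
  chain <- chain_append(chain, g)
  ev <- recovery_eval(sim$truth, chain, "b")
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)

  g0 <- g; g0@output_barcodes <- character(0); g0@output_count <- 0L
  chain0 <- chain_append(gate_chain(oc), g0)
  ev0 <- recovery_eval(sim$truth, chain0, "b")
  expect_true(ev0$empty_output)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  expect_error(recovery_eval(sim$truth, chain, "martian"), "martian")
})
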