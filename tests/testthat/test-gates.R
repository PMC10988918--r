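test_that("apply_gate enumerates the toy fixture exactly", {
  oc <- toy_container()
  # CD3 in [1,3] and CD4 in [1,3] holds only for cells 2 (2.0, 1.8)
  # and 5 (1.9, 1.7)
  g <- apply_gate(oc, "CD3+CD4+", "ADT", "CD3", "ADT", "CD4",
                  rectangle_gate(1, 3, 1, 3))
  expect_equal(g@output_barcodes, c("c2", "c5"))
  expect_equal(g@input_count, 5L)
  expect_equal(g@output_count, 2L)
  expect_equal(g@value_source, "normalized")
})

test_that("identity and empty gates behave per contract", {
  oc <- toy_container()
  full <- apply_gate(oc, "all", "ADT", "CD3", "ADT", "CD4",
                     rectangle_gate(-10, 10, -10, 10))
  expect_identical(full@output_barcodes, full@input_barcodes)
  expect_warning(
    none <- apply_gate(oc, "none", "ADT", "CD3", "ADT", "CD4",
                       rectangle_gate(100, 200, 100, 200)),
    "caught no cells")
  expect_equal(none@output_count, 0L)
  expect_error(apply_gate(oc, "x", "ADT", "CD3", "ADT", "CD4",
                          rectangle_gate(0, 1, 0, 1),
                          input_barcodes = character(0)),
               "empty")
  expect_error(apply_gate(oc, "x", "ADT", "CD99", "ADT", "CD4",
                          rectangle_gate(0, 1, 0, 1)),
               "CD99")
})

test_that("chains pass barcodes between gates and number them sequentially", {
  sim <- small_pbmc()
  oc <- sim$container
  thr <- suggest_thresholds(oc)
  rng <- apply(oc@assays$ADT$normalized, 2, range)
  chain <- gate_chain(oc, name = "cd8_two_step")
  g1 <- apply_gate(oc, "CD19-/CD3+", "ADT", "CD19", "ADT", "CD3",
                   rectangle_gate(rng[1, "CD19"] - 1, thr[["CD19"]],
                                  thr[["CD3"]], rng[2, "CD3"] + 1))
  chain <- chain_append(chain, g1)
  g2 <- apply_gate(oc, "CD8+/CD4-", "ADT", "CD8", "ADT", "CD4",
                   rectangle_gate(thr[["CD8"]], rng[2, "CD8"] + 1,
                                  rng[1, "CD4"] - 1, thr[["CD4"]]),
                   input_barcodes = g1@output_barcodes)
  chain <- chain_append(chain, g2)
  expect_equal(vapply(chain@gates, function(g) g@counter, integer(1)), 1:2)
  expect_true(all(g2@output_barcodes %in% g1@output_barcodes))
  expect_true(all(g1@output_barcodes %in% chain@root_barcodes))

  # stale input: a gate built from the root cannot follow gate 2
  stale <- apply_gate(oc, "stale", "ADT", "CD3", "ADT", "CD4",
                      rectangle_gate(-10, 10, -10, 10))
  expect_error(chain_append(chain, stale), "frontier")
})

test_that("chain summary percentages multiply through the hierarchy", {
  sim <- small_pbmc()
  oc <- sim$container
  chain <- replay(pbmc_scheme(oc, "cd8_t"), oc)
  s <- summarize_chain(chain)
  expect_equal(nrow(s), 2L)
  expect_equal(s$pct_of_root[2],
               s$pct_of_parent[1] * s$pct_of_parent[2] / 100)
  # identity gate summary shows 100% of parent
  id <- chain_append(gate_chain(oc),
                     apply_gate(oc, "all", "ADT", "CD3", "ADT", "CD4",
                                rectangle_gate(-100, 100, -100, 100)))
  expect_equal(summarize_chain(id)$pct_of_parent, 100)
})

test_that("gate output sets are invariant to container cell order", {
  sim <- small_pbmc()
  oc <- sim$container
  perm <- withr::with_seed(13, sample(n_cells(oc)))
  shuffled <- subset_cells(oc, oc@barcodes)      # copy
  # rebuild a permuted container from the same data
  shuffled <- omics_container(
    oc@barcodes[perm],
    assays = list(ADT = list(raw = oc@assays$ADT$raw[perm, ],
                             normalized = oc@assays$ADT$normalized[perm, ],
                             features = oc@assays$ADT$features)),
    norm_record = oc@norm_record)
  geom <- rectangle_gate(1, 8, 1, 8)
  a <- apply_gate(oc, "g", "ADT", "CD3", "ADT", "CD4", geom)
  b <- apply_gate(shuffled, "g", "ADT", "CD3", "ADT", "CD4", geom)
  expect_setequal(a@output_barcodes, b@output_barcodes)
})

test_that("chains are monotone: every gate output nests in its input", {
  sim <- small_pbmc()
  oc <- sim$container
  set.seed(31)
  feats <- oc@assays$ADT$features
  for (rep in 1:10) {
    chain <- gate_chain(oc)
    frontier <- oc@barcodes
    for (k in 1:3) {
      fx <- sample(feats, 1); fy <- sample(setdiff(feats, fx), 1)
      vx <- feature_values(oc, "ADT", fx, frontier)
      vy <- feature_values(oc, "ADT", fy, frontier)
      geom <- rectangle_gate(quantile(vx, 0.1), quantile(vx, 0.9) + 1e-9,
                             quantile(vy, 0.1), quantile(vy, 0.9) + 1e-9)
      g <- suppressWarnings(
        apply_gate(oc, sprintf("g%d", k), "ADT", fx, "ADT", fy, geom,
                   input_barcodes = frontier))
      chain <- chain_append(chain, g)
      frontier <- g@output_barcodes
      if (!length(frontier)) break
    }
    outs <- lapply(chain@gates, function(g) g@output_barcodes)
    sets <- c(list(chain@root_barcodes), outs)
    for (k in seq_along(outs)) {
      expect_true(all(sets[[k + 1]] %in% sets[[k]]))
    }
  }
})
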