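# adtgate

Flow-cytometry-style gating of CITE-Seq surface-protein data, headless and
scriptable.

CITE-Seq measures the RNA transcriptome and the cell-surface proteome
(through antibody-derived tags, ADTs) in the same cell. Because ADT signal
is dense and tracks the surface markers flow cytometrists already use,
cell populations can be classified the way they are in flow cytometry:
plot two markers, draw a boundary ("gate") around the cells of interest,
re-plot the selected cells on a new marker pair, and repeat. `adtgate`
implements that iterative filtration workflow as a library and command line
for people who want gating to be reproducible, auditable, and runnable in a
pipeline rather than by hand:

- **Provenance-carrying gates.** Each filtration step is a `Gate` S4 object
  recording the marker pair, the selection geometry, the input and output
  cell barcodes and their counts, a label, and a counter. Gates are linked
  into a `GateChain` by barcode passing: gate *k*'s input set is exactly
  gate *k−1*'s output set.
- **Replayable schemes.** A chain exports both a full audit trail (JSON,
  with barcodes) and a compact gating scheme (YAML, geometry + axes only)
  that replays deterministically on any container with the same features.
- **CLR normalization.** ADT counts are normalized with the centered
  log-ratio transform: within each margin vector,
  `y_i = ln(1 + x_i) − mean_j ln(1 + x_j)` (a pure log-ratio variant with a
  configurable pseudocount is also provided). Gating always reads
  normalized ADT values unless raw gating is requested explicitly.
- **Back-gating.** Select cells in an embedding (UMAP/PCA/tSNE coordinates
  are inputs, never computed here) or by a metadata annotation, and project
  the selection onto any marker pair to see which antibodies separate it.
- **Multi-omic QC.** Per-cell totals and detection counts for RNA and ADT,
  split by any categorical metadata, with one-way ANOVA and Tukey HSD
  (studentized-range) pairwise comparison across groups.
- **A synthetic PBMC generator.** Negative-binomial ADT counts with
  population-specific marker profiles, sparse RNA, Gaussian embedding
  clusters, donor structure — with ground-truth labels, so every part of
  the workflow is testable end to end.

Input formats: 10x-style MTX triplet directories (feature types split into
`RNA` and `ADT` assays), the package's own plain-text container bundle, and
CSV matrices. Native R serialized objects are deliberately not parsed.

## Worked example

Gate CD8 T cells with the canonical two-step scheme (CD19−/CD3+ to isolate
T cells, then CD8+/CD4−) on a synthetic 5,000-cell PBMC-like dataset:

```r
library(adtgate)

sim <- generate_synthetic(pbmc_preset(n_cells = 5000, seed = 1))
oc  <- normalize_adt(sim$container)          # CLR, across-cells margin
chain <- replay(pbmc_scheme(oc, "cd8_t"), oc)
chain
#> GateChain 'pbmc_cd8_t': 2 gate(s), root 5000 cells
#>   counter      label input_count output_count pct_of_parent pct_of_root
#> 1       1 CD19-/CD3+        5000         2224      44.48000       44.48
#> 2       2  CD8+/CD4-        2224          687      30.89029       13.74
```

The first gate keeps 44.5% of cells (the T-cell compartment), the second
keeps 30.9% of those — 13.7% of all cells, matching the planted CD8 T
fraction of 15% after sampling noise. Against the generator's ground truth:

```r
recovery_eval(sim$truth, chain, "cd8_t")[c("precision", "recall", "f1")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $f1
#> [1] 1
```

Back-gate the NK cluster (selected by its annotation) onto the CD56/CD3
marker pair; NK cells should be CD56-positive and CD3-negative:

```r
sel <- select_by_metadata(oc, "cluster", "nk")
tab <- backgate_table(oc, sel, "ADT", "CD56", "ADT", "CD3")
attr(tab, "summary")[c("n_highlighted", "median_x_in", "median_x_out",
                       "median_y_in", "median_y_out")]
#> $n_highlighted
#> [1] 517
#> $median_x_in
#> [1] 3.421
#> $median_x_out
#> [1] -0.454
#> $median_y_in
#> [1] -1.749
#> $median_y_out
#> [1] -0.546
```

The highlighted cells sit far right (CD56) and low (CD3) of everyone else —
exactly the NK profile.

A shell entry point wrapping the same functions ships at
`inst/cli/adtgate.R` with `simulate`, `gate`, `qc` and `backgate`
subcommands; every run writes a machine-readable manifest alongside its
outputs.

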