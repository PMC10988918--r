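---
title: "Methods: gating CITE-Seq surface proteins with adtgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating CITE-Seq surface proteins with adtgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtgate)
```

## The model

`adtgate` treats cell-population classification as iterative filtration on
two-dimensional marker scatters, the way flow cytometry does. A dataset is
an `OmicsContainer`: one or more assays (cells × features count matrices;
`ADT` for antibody-derived tags, `RNA` for transcripts), optional
low-dimensional embeddings, and per-cell metadata, all keyed by cell
barcode. Barcodes — never row positions — are the identifier passed between
every operation, which is what makes a gating history auditable: a `Gate`
stores its input and output barcode sets, and a `GateChain` enforces that
gate *k* draws exactly from gate *k−1*'s output. The chain invariant gives
subset monotonicity (root ⊇ out₁ ⊇ out₂ ⊇ …) by construction, and any
chain can be exported as a compact scheme and replayed bit-for-bit.

The workflow assumes embeddings and any clustering annotations are computed
upstream; `adtgate` consumes them and never runs dimension reduction. It
also performs no cell filtering or denoising: quality control here is
descriptive, not corrective.

## ADT normalization

Antibody capture is compositional — per-cell tag totals vary for technical
reasons — so gating operates on centered log-ratio (CLR) values, not raw
counts. Two choices are deliberately exposed:

* **Margin** (`across_cells`, the default, vs `within_cell`). Centering
  each feature across cells is the common practice for ADT panels in the
  mainstream single-cell toolchain and keeps each marker's negative/positive
  modes comparable across features; centering within a cell across the
  panel is the textbook compositional direction. Both are supported because
  the CLR literature fixes neither, and the choice is recorded in the
  container's normalization record and in every exported scheme, so a
  replay can warn when the records disagree.
* **Variant** (`log1p_centered`, the default, vs `pure_log_ratio`).
  `log(1 + x)` centered by its margin mean is the formula the dominant
  toolchain implements and tolerates zeros without a tunable offset;
  `log(x + c) − mean(log(x + c))` with pseudocount `c > 0` (default 1) is
  available for textbook fidelity.

An all-zero margin vector maps to zeros rather than NaN: a feature nobody
detected carries no information and must not poison downstream gating.
Externally normalized matrices (e.g. background-denoised values) are
accepted as-is with `method = "external"`. RNA gets ordinary library-size
log-normalization (`log(1 + s·x/total)`, default scale `s = 10^4`); it is
optional because gating reads ADT.

## Gate geometry

Gates are rectangles or polygons. Two conventions are fixed here because
the field's practice is implicit:

* **Boundary-inclusive membership** for both geometries — a cell exactly on
  the gate edge is inside, the usual flow-cytometry reading of a drawn
  boundary.
* **Even-odd fill rule** for polygons, implemented by ray casting with an
  explicit on-edge test. Free-hand lassos can self-intersect; the even-odd
  rule matches what selection tools render, so self-intersecting polygons
  are accepted with a warning. A non-self-intersecting outline with zero
  area is rejected as degenerate.

Membership comparisons are exact floating point, with no epsilon: the
predicate is geometric, and gate coordinates originate from drawn
selections where a tolerance has no meaning. The same predicate backs both
forward gating and embedding-space selection (a single source of truth,
verified in the tests against an independent winding-number oracle on
random simple polygons). Scheme files serialize coordinates with 17
significant digits — the number that uniquely identifies a double — so an
export/import/replay cycle reproduces every output count exactly.

## Back-gating and density

A back-gate selects cells in the first two dimensions of a named embedding
(or by a metadata category, or an explicit list) and projects the selection
onto a marker pair, returning a per-cell table with a highlight flag plus
group medians. The density underlay for scatter plots is a 2-D histogram
over the data's bounding box (default 64×64), optionally smoothed with one
bilinear pass that preserves the total count; a histogram was chosen over
kernel density because it is cheap, deterministic, and conservation of the
cell count is checkable exactly.

## Quality control and group comparison

Per-cell QC metrics are computed from raw counts — totals and
detection counts (feature with raw count > 0) per assay — because detection
is a property of the measurement, not of any normalization. "Detected
antibodies per cell" is the count of ADT features with nonzero raw counts:
the only threshold-free definition.

`group_compare` fits a one-way fixed-effects ANOVA of a metric against a
categorical variable and runs Tukey's HSD on all pairs, with adjusted
p-values from the studentized-range distribution at the within-group
degrees of freedom (Tukey–Kramer for unbalanced groups). The implementation
delegates to `stats::aov`/`stats::TukeyHSD` and is validated in the test
suite against an independent `ptukey`-based computation and against the
two-group identity padj = ANOVA p. Groups with fewer than two cells are
dropped with a warning. Note the procedure assumes homogeneous within-group
variance; strong detection-thinning effects (below) make the affected
groups noisier, which mildly inflates pairwise false positives among
high-variance groups — visible in the validation simulations and documented
rather than patched, since Tukey HSD is the field's reporting convention.

Co-expression tables classify cells into quadrants against per-feature
positivity thresholds; the default threshold (upper quartile of normalized
values) is deliberately simple and always overridable, because positivity
has no universal definition in manual gating culture.

## The synthetic generator

The generator exists so that gating, back-gating and QC can be validated
against known ground truth. A `synthetic_spec` defines a population
mixture; per population, ADT counts are negative binomial with mean
`exp(log_mean)` and dispersion θ (variance μ + μ²/θ), RNA counts are
negative binomial thinned by a dropout probability, and the embedding is
the population's center plus isotropic Gaussian noise. Donor labels are
uniform; a donor effect is Bernoulli thinning of ADT entries, which lowers
the detected-antibody count for that donor's cells. All draws run inside a
locally seeded RNG, so generation is reproducible and never perturbs the
caller's random state.

The PBMC preset models eight populations over a nine-antibody panel with
the canonical marker logic (CD4 T: CD3+CD4+; CD8 T: CD3+CD8+; classical
monocytes: CD14+CD16−; non-classical: CD16+; an intermediate CD14+CD16+
subpopulation; NK: CD56+CD16+CD3−; B: CD19+; platelets: CD41+ with a
5-fold reduced RNA mean). CD41 is used as the platelet marker because it is
the canonical platelet integrin. Positive markers sit at log-mean 5
(≈148 counts) and negative at log-mean 1 (≈2.7), dispersion 8: on the CLR
axis the two modes are separated by several standard deviations, so a gate
at the midpoint between modes recovers each planted population — this is
the designed condition under which the recovery tests assert precision and
recall ≥ 0.95. Mixture proportions (30/15/20/5/3/10/12/5%) are typical of
peripheral blood with a small platelet contaminant. Embedding clusters sit
on a circle of radius 10 with SD 0.8, far enough apart that a ±3 SD box
isolates one population.

Thresholds for the preset's schemes are data-driven: per feature, 1-D
k-means with k = 2 initialized at the 5th and 95th percentiles
(deterministic given the data) and the boundary at the midpoint of the two
centers.

The donor analog of a two-block patient structure applies thinning only to
donors 5–8 (`donor_block_dropout = c(0, 0.25)`); with ~100 cells per donor
the between-block difference in detected antibodies is overwhelming (Tukey
padj numerically 0) while within-block pairs are true nulls. The default
preset disables donor effects, because thinning would corrupt the marker
signal the recovery experiments gate on; the two configurations represent
two different experiments.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: ambient-antibody background and its denoising,
RNA co-expression structure, doublets, batch effects beyond donor thinning,
overlapping or non-Gaussian embedding geometry, and the continuum between
biological populations. Real gates need human judgment about boundary
placement; the preset's midpoint rule works because the modes are planted.

## Validation problem sizes

The shipped suite uses a 2,000-cell preset container for module tests; a
10,000-cell container for the scheme-recovery and back-gate checks; 100
random gate chains for the chain/replay invariants; 10⁵ random
polygon/point pairs against the winding-number oracle; 100 donor-block
simulations of 800 cells and 400 null simulations of 1,000 cells for the
group-comparison calibration. `scripts/acceptance.R` re-runs the same
computations from a single command-line seed.

## Limitations

Gating on RNA features is permitted (any assay/feature pair resolves) but
RNA sparsity makes such scatters hard to interpret — surface protein is the
reliable axis. Only the first two embedding dimensions participate in
back-gating. Boolean gate algebra (AND/OR across sibling gates), 1-D
interval gates, and GatingML interchange are out of scope; the scheme
format carries a schema version so such extensions can fail loudly rather
than silently.
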