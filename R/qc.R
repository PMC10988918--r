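#' Per-cell multi-omic QC metrics
#'
#' Computes the standard CITE-Seq quality metrics from RAW counts: total RNA
#' counts, number of genes detected (raw count > 0), total ADT counts, and
#' number of detected antibodies (ADT features with raw count > 0). Metrics
#' for an absent assay are omitted, not zero-filled. Cell metadata columns
#' are joined so the table can be split by any categorical annotation.
#'
#' @param container an [OmicsContainer-class].
#' @return data.frame with one row per cell (`barcode` first column),
#'   available metrics, and all cell_meta columns.
#' @export
compute_qc <- function(container) {
  out <- data.frame(barcode = container@barcodes, stringsAsFactors = FALSE)
  if ("RNA" %in% names(container@assays)) {
    r <- container@assays$RNA$raw
    out$total_rna_counts <- as.numeric(Matrix::rowSums(r))
    out$n_genes_detected <- as.integer(Matrix::rowSums(r > 0))
  }
  if ("ADT" %in% names(container@assays)) {
    a <- container@assays$ADT$raw
    out$total_adt_counts <- as.numeric(Matrix::rowSums(a))
    out$n_antibodies_detected <- as.integer(Matrix::rowSums(a > 0))
  }
  if (ncol(container@cell_meta)) {
    out <- cbind(out, container@cell_meta, row.names = NULL)
  }
  out
}

#' Compare a QC metric across groups: one-way ANOVA + Tukey HSD
#'
#' Fits a one-way fixed-effects ANOVA of `metric ~ group_var` and performs
#' Tukey's honestly-significant-difference test on all group pairs, with
#' adjusted p-values from the studentized-range distribution at the
#' within-group degrees of freedom. Groups with fewer than 2 cells are
#' dropped with a warning; at least 2 groups must remain.
#'
#' @param qc a QC table from [compute_qc()] (any data.frame works).
#' @param metric name of the numeric metric column.
#' @param group_var name of the categorical grouping column.
#' @param alpha significance level used to flag pairs (default 0.05).
#' @return an object of class `group_comparison`: a list with `metric`,
#'   `group_var`, `groups` (per-group n/mean/sd), `anova` (F, df, p), and
#'   `pairs` (data.frame group_i, group_j, diff, lwr, upr, padj,
#'   significant).
#' @export
group_compare <- function(qc, metric, group_var, alpha = 0.05) {
  if (!metric %in% names(qc)) stop_fmt("metric '%s' not in QC table", metric)
  if (!group_var %in% names(qc)) {
    stop_fmt("group variable '%s' not in QC table", group_var)
  }
  y <- qc[[metric]]
  g <- as.character(qc[[group_var]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warn_fmt("dropping group(s) with < 2 cells: %s",
             paste(small, collapse = ", "))
    keep2 <- !g %in% small
    y <- y[keep2]; g <- g[keep2]
  }
  if (length(unique(g)) < 2L) {
    stop_fmt("group_compare needs at least 2 groups with >= 2 cells")
  }
  g <- factor(g)
  fit <- aov(y ~ g)
  an <- summary(fit)[[1L]]
  fstat <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pr <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(
    group_i = vapply(pr, `[`, "", 1L),
    group_j = vapply(pr, `[`, "", 2L),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    padj = tk[, "p adj"],
    stringsAsFactors = FALSE, row.names = NULL)
  pairs$significant <- pairs$padj < alpha
  groups <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, stats::sd)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(metric = metric, group_var = group_var, alpha = alpha,
                 groups = groups,
                 anova = list(F = fstat, df_between = an$Df[1L],
                              df_within = an$Df[2L], p = pval),
                 pairs = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s: ANOVA F(%d, %d) = %.3f, p = %.3g\n",
              x$metric, x$group_var, x$anova$df_between, x$anova$df_within,
              x$anova$F, x$anova$p))
  print(x$pairs[, c("group_i", "group_j", "diff", "padj", "significant")])
  invisible(x)
}

#' Write a group comparison's pairwise table to TSV
#' @param comparison a `group_comparison`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_group_comparison <- function(comparison, path) {
  write.table(comparison$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Cross-assay co-expression quadrant table
#'
#' For a feature pair (possibly across assays, e.g. an RNA transcript versus
#' its ADT protein), classifies every cell into a quadrant against
#' per-feature positivity thresholds: `double_negative`, `a_only`, `b_only`,
#' or `double_positive` (threshold-inclusive on the positive side). Default
#' thresholds are each feature's upper quartile of the normalized values —
#' positivity has no universal definition in manual gating culture, so the
#' default is deliberately simple and overridable.
#'
#' @param container an [OmicsContainer-class].
#' @param assay_a,feature_a,assay_b,feature_b the feature pair.
#' @param thresholds length-2 numeric `(thr_a, thr_b)`; `NULL` for the
#'   upper-quartile default.
#' @param value_source `"normalized"` (default) or `"raw"`.
#' @return data.frame (barcode, value_a, value_b, quadrant) with attribute
#'   `thresholds`.
#' @export
coexpression_table <- function(container, assay_a, feature_a,
                               assay_b, feature_b, thresholds = NULL,
                               value_source = c("normalized", "raw")) {
  value_source <- match.arg(value_source)
  va <- feature_values(container, assay_a, feature_a, source = value_source)
  vb <- feature_values(container, assay_b, feature_b, source = value_source)
  if (is.null(thresholds)) {
    thresholds <- c(quantile(va, 0.75, names = FALSE),
                    quantile(vb, 0.75, names = FALSE))
  }
  if (length(thresholds) != 2L) stop_fmt("thresholds must have length 2")
  pa <- va >= thresholds[1L]
  pb <- vb >= thresholds[2L]
  quadrant <- ifelse(pa & pb, "double_positive",
              ifelse(pa, "a_only",
              ifelse(pb, "b_only", "double_negative")))
  out <- data.frame(barcode = container@barcodes,
                    value_a = as.numeric(va), value_b = as.numeric(vb),
                    quadrant = quadrant, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}
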