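#' Centered log-ratio transform of a count matrix
#'
#' The CLR transform is the standard normalization for antibody-derived tag
#' (ADT) counts: within each margin vector, log-transformed counts are
#' centered by their mean so that antibody abundances become comparable
#' across cells despite compositional capture effects.
#'
#' Two margins are supported: `"across_cells"` centers each feature's values
#' over all cells (the common practice for ADT panels and the default here);
#' `"within_cell"` centers each cell's values across its features (the
#' textbook compositional-data direction). Two variants of the log are
#' supported: `"log1p_centered"` computes `log(1 + x) - mean(log(1 + x))`
#' (the formula implemented by the mainstream single-cell toolchain), and
#' `"pure_log_ratio"` computes `log(x + c) - mean(log(x + c))` with
#' pseudocount `c`. A margin vector that is all zeros maps to zeros, not NaN.
#'
#' @param raw non-negative cells x features count matrix (dense or sparse).
#' @param margin `"across_cells"` or `"within_cell"`.
#' @param variant `"log1p_centered"` or `"pure_log_ratio"`.
#' @param pseudocount positive offset `c` for the pure log-ratio variant.
#' @return dense numeric matrix, same shape and dimnames as `raw`; every
#'   margin vector of the output has mean zero.
#' @examples
#' clr_normalize(matrix(c(0, 3, 15), 1, 3), margin = "within_cell")
#' @export
clr_normalize <- function(raw,
                          margin = c("across_cells", "within_cell"),
                          variant = c("log1p_centered", "pure_log_ratio"),
                          pseudocount = 1) {
  margin <- match.arg(margin)
  variant <- match.arg(variant)
  if (pseudocount <= 0) stop_fmt("pseudocount must be > 0")
  m <- as.matrix(raw)
  if (any(m < 0)) stop_fmt("clr_normalize requires non-negative counts")
  lg <- if (variant == "log1p_centered") log1p(m) else log(m + pseudocount)
  if (margin == "within_cell") {
    out <- lg - rowMeans(lg)
    zero <- rowSums(m) == 0
    out[zero, ] <- 0
  } else {
    out <- sweep(lg, 2L, colMeans(lg))
    zero <- colSums(m) == 0
    out[, zero] <- 0
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Library-size log-normalization for RNA counts
#'
#' Per cell, `y = log(1 + scale_factor * x / total_counts_of_cell)`. Cells
#' with zero total counts map to zeros with a warning. RNA normalization is
#' optional for the gating workflow (which reads ADT values) but recommended
#' for feature plots.
#'
#' @param raw non-negative cells x genes count matrix.
#' @param scale_factor positive scaling constant (default 10000).
#' @return dense numeric matrix of the same shape.
#' @export
log_normalize_rna <- function(raw, scale_factor = 1e4) {
  if (scale_factor <= 0) stop_fmt("scale_factor must be > 0")
  m <- as.matrix(raw)
  if (any(m < 0)) stop_fmt("log_normalize_rna requires non-negative counts")
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warn_fmt("%d cell(s) with zero total RNA counts normalized to zeros",
             sum(zero))
    tot[zero] <- 1
  }
  out <- log1p(scale_factor * m / tot)
  out[zero, ] <- 0
  dimnames(out) <- dimnames(m)
  out
}

#' Normalize the ADT assay of a container
#'
#' Fills the ADT assay's normalized slot using [clr_normalize()] (or leaves
#' an externally supplied matrix untouched for `method = "external"`) and
#' records the method, margin, variant and pseudocount in the container's
#' normalization record so that exported gating schemes carry full
#' normalization provenance.
#'
#' @param container an [OmicsContainer-class] with an ADT assay.
#' @param method `"clr"`, `"none"` or `"external"`.
#' @param margin,variant,pseudocount passed to [clr_normalize()].
#' @return the container with ADT normalized slot and `norm_record` set.
#' @export
normalize_adt <- function(container, method = c("clr", "none", "external"),
                          margin = "across_cells",
                          variant = "log1p_centered", pseudocount = 1) {
  method <- match.arg(method)
  if (!"ADT" %in% names(container@assays)) {
    stop_fmt("container has no ADT assay to normalize")
  }
  if (method == "external") {
    if (is.null(container@assays$ADT$normalized)) {
      stop_fmt("method = \"external\" requires a pre-filled ADT normalized matrix")
    }
    container@norm_record <- list(method = "external")
    return(container)
  }
  if (method == "none") {
    container@norm_record <- list(method = "none")
    return(container)
  }
  container@assays$ADT$normalized <- clr_normalize(
    container@assays$ADT$raw, margin = margin, variant = variant,
    pseudocount = pseudocount)
  container@norm_record <- list(method = "clr", margin = margin,
                                variant = variant, pseudocount = pseudocount)
  container
}
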