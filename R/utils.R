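#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom Matrix Matrix readMM writeMM t rowSums colSums
#' @importFrom stats aov TukeyHSD rnbinom rnorm rbinom runif median
#'   quantile kmeans setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Run an expression with a local RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this
# so no function perturbs global random state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Full-precision numeric formatting that round-trips doubles exactly.
fmt_full <- function(x) sprintf("%.17g", x)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
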