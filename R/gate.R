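#' Gate: one filtration event
#'
#' A `Gate` records everything about a single filtration step of the gating
#' workflow: the feature pair it was drawn on, the selection geometry, the
#' cell barcodes that entered and the barcodes that passed, their counts, a
#' user label, a 1-based counter giving its position in its chain, a creation
#' timestamp, and whether the values were read from the normalized or raw
#' slot. Everything but the output barcodes is intrinsic to the gate; the
#' output barcodes are what one gate passes to the next.
#'
#' @slot counter 1-based ordinal within its chain (0 until chained).
#' @slot label user-provided gate label.
#' @slot assay_x,feature_x,assay_y,feature_y axis definitions resolving into
#'   the container the gate was applied to.
#' @slot geometry a `gate_geometry` (see [rectangle_gate()]).
#' @slot input_barcodes,output_barcodes barcode sets, container order.
#' @slot input_count,output_count set sizes.
#' @slot created_at creation timestamp.
#' @slot value_source `"normalized"` or `"raw"`.
#' @export
setClass("Gate", representation(
  counter = "integer",
  label = "character",
  assay_x = "character", feature_x = "character",
  assay_y = "character", feature_y = "character",
  geometry = "list",
  input_barcodes = "character", output_barcodes = "character",
  input_count = "integer", output_count = "integer",
  created_at = "POSIXct",
  value_source = "character"
))

setValidity("Gate", function(object) {
  if (!all(object@output_barcodes %in% object@input_barcodes)) {
    return("output_barcodes must be a subset of input_barcodes")
  }
  if (object@input_count != length(object@input_barcodes) ||
      object@output_count != length(object@output_barcodes)) {
    return("counts must equal barcode set sizes")
  }
  TRUE
})

#' @export
setMethod("show", "Gate", function(object) {
  cat(sprintf("Gate %s'%s': %s/%s vs %s/%s [%s], %d -> %d cells\n",
              if (object@counter > 0L) sprintf("#%d ", object@counter) else "",
              object@label,
              object@assay_x, object@feature_x,
              object@assay_y, object@feature_y,
              object@geometry$kind,
              object@input_count, object@output_count))
})

#' Apply a gate to a container
#'
#' Evaluates the membership predicate on the (feature_x, feature_y) values of
#' the input cells and returns a fully populated [Gate-class]. ADT values are
#' read from the normalized slot by default (the workflow requires normalized
#' antibody counts); gating on raw values must be requested explicitly and is
#' recorded in `value_source`. A gate that catches no cells is legal and
#' returned with `output_count = 0` plus a warning.
#'
#' @param container an [OmicsContainer-class].
#' @param label user label for the gate.
#' @param assay_x,feature_x,assay_y,feature_y axes; features must exist.
#' @param geometry a `gate_geometry`.
#' @param input_barcodes cells the gate draws from (default: all cells).
#' @param value_source `"normalized"` (default) or `"raw"`.
#' @return a [Gate-class] with `counter = 0` (assigned by [chain_append()]).
#' @export
apply_gate <- function(container, label, assay_x, feature_x,
                       assay_y, feature_y, geometry,
                       input_barcodes = container@barcodes,
                       value_source = c("normalized", "raw")) {
  value_source <- match.arg(value_source)
  if (!container@gateable) {
    stop_fmt("container has no ADT assay and is not gateable")
  }
  if (!length(input_barcodes)) stop_fmt("input barcode set is empty")
  # keep container order so audit files are byte-stable
  input_barcodes <- container@barcodes[container@barcodes %in% input_barcodes]
  vx <- feature_values(container, assay_x, feature_x, input_barcodes,
                       source = value_source)
  vy <- feature_values(container, assay_y, feature_y, input_barcodes,
                       source = value_source)
  inside <- points_in_geometry(vx, vy, geometry)
  out <- input_barcodes[inside]
  if (!length(out)) {
    warn_fmt("gate '%s' caught no cells", label)
  }
  methods::new("Gate",
    counter = 0L, label = as.character(label),
    assay_x = assay_x, feature_x = feature_x,
    assay_y = assay_y, feature_y = feature_y,
    geometry = unclass(geometry),
    input_barcodes = input_barcodes, output_barcodes = out,
    input_count = length(input_barcodes), output_count = length(out),
    created_at = Sys.time(), value_source = value_source)
}

gate_geometry_of <- function(gate) {
  structure(gate@geometry, class = "gate_geometry")
}

#' GateChain: an ordered, provenance-carrying list of gates
#'
#' A chain starts from a root barcode set (normally the whole container) and
#' passes each gate's output barcodes to the next gate's input. The chain
#' carries scheme metadata: a name, a structural fingerprint of the container
#' it was built on, and the ADT normalization record, so a scheme exported
#' from the chain is replayable with full provenance.
#'
#' @slot gates list of [Gate-class], counters 1..N in order.
#' @slot root_barcodes the full cell set the first gate drew from.
#' @slot name scheme name.
#' @slot container_fingerprint structural digest of the source container.
#' @slot normalization ADT normalization record at gating time.
#' @export
setClass("GateChain", representation(
  gates = "list",
  root_barcodes = "character",
  name = "character",
  container_fingerprint = "character",
  normalization = "list"
))

setValidity("GateChain", function(object) {
  gs <- object@gates
  if (!length(gs)) return(TRUE)
  if (!identical(vapply(gs, function(g) g@counter, integer(1)),
                 seq_along(gs))) {
    return("gate counters must be 1..N in order")
  }
  if (!setequal(gs[[1L]]@input_barcodes, object@root_barcodes)) {
    return("first gate's input must equal root_barcodes")
  }
  for (k in seq_along(gs)[-1L]) {
    if (!setequal(gs[[k]]@input_barcodes, gs[[k - 1L]]@output_barcodes)) {
      return(sprintf("gate %d input does not match gate %d output", k, k - 1L))
    }
  }
  TRUE
})

#' Create an empty gate chain
#'
#' @param container the [OmicsContainer-class] the chain will gate.
#' @param name scheme name stored in the chain metadata.
#' @return an empty [GateChain-class] rooted at all container cells.
#' @export
gate_chain <- function(container, name = "scheme") {
  methods::new("GateChain",
    gates = list(), root_barcodes = container@barcodes,
    name = as.character(name),
    container_fingerprint = container_fingerprint(container),
    normalization = container@norm_record)
}

#' Append a gate to a chain
#'
#' The gate's input barcodes must equal the previous gate's output barcodes
#' (or the root set for the first gate) — the barcode-passing invariant that
#' makes a chain an auditable filtration history. The gate's counter is
#' assigned the next ordinal.
#'
#' @param chain a [GateChain-class].
#' @param gate a [Gate-class] built from the chain's current frontier.
#' @return the extended chain.
#' @export
chain_append <- function(chain, gate) {
  expected <- if (length(chain@gates)) {
    chain@gates[[length(chain@gates)]]@output_barcodes
  } else {
    chain@root_barcodes
  }
  if (!setequal(gate@input_barcodes, expected)) {
    stop_fmt(
      "gate input does not match chain frontier: %d cells missing, %d unexpected",
      length(setdiff(expected, gate@input_barcodes)),
      length(setdiff(gate@input_barcodes, expected)))
  }
  gate@counter <- length(chain@gates) + 1L
  chain@gates <- c(chain@gates, list(gate))
  methods::validObject(chain)
  chain
}

#' Current frontier of a chain
#'
#' The output barcodes of the last gate (the root set if the chain is empty):
#' the cells the next gate would draw from.
#'
#' @param chain a [GateChain-class].
#' @return character vector of barcodes.
#' @export
chain_frontier <- function(chain) {
  if (length(chain@gates)) {
    chain@gates[[length(chain@gates)]]@output_barcodes
  } else {
    chain@root_barcodes
  }
}

#' Flow-cytometry-style hierarchy summary of a chain
#'
#' @param chain a [GateChain-class].
#' @return data.frame with one row per gate: counter, label, input_count,
#'   output_count, pct_of_parent, pct_of_root.
#' @export
summarize_chain <- function(chain) {
  n_root <- length(chain@root_barcodes)
  rows <- lapply(chain@gates, function(g) {
    data.frame(
      counter = g@counter, label = g@label,
      input_count = g@input_count, output_count = g@output_count,
      pct_of_parent = if (g@input_count > 0)
        100 * g@output_count / g@input_count else 0,
      pct_of_root = if (n_root > 0) 100 * g@output_count / n_root else 0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
setMethod("show", "GateChain", function(object) {
  cat(sprintf("GateChain '%s': %d gate(s), root %d cells\n",
              object@name, length(object@gates),
              length(object@root_barcodes)))
  if (length(object@gates)) {
    print(summarize_chain(object))
  }
})
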