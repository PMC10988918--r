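scheme_schema_version <- "1.0"

#' Export a gate chain: audit trail and replayable scheme
#'
#' Writes two artifacts. The audit file (JSON) is the full record: per gate
#' the axes, geometry, input/output barcodes and counts, timestamps, plus the
#' container fingerprint and normalization record — everything needed to
#' reconstruct what happened. The scheme file (YAML) is the replayable
#' recipe: axes, geometry and labels only, no barcodes, so it can be applied
#' to another container with [replay()]. Barcode sets are written in
#' container order, making audit files byte-stable across replays (modulo
#' timestamps).
#'
#' @param chain a [GateChain-class].
#' @param audit_path output path for the audit JSON (NULL to skip).
#' @param scheme_path output path for the scheme YAML (NULL to skip).
#' @return invisibly, a list with the written paths.
#' @export
export_chain <- function(chain, audit_path = NULL, scheme_path = NULL) {
  stopifnot(methods::is(chain, "GateChain"))
  if (!is.null(audit_path)) {
    audit <- list(
      schema_version = scheme_schema_version,
      name = chain@name,
      container_fingerprint = chain@container_fingerprint,
      normalization = chain@normalization,
      root_count = length(chain@root_barcodes),
      gates = lapply(chain@gates, function(g) list(
        counter = g@counter, label = g@label,
        assay_x = g@assay_x, feature_x = g@feature_x,
        assay_y = g@assay_y, feature_y = g@feature_y,
        geometry = geometry_to_list(gate_geometry_of(g)),
        value_source = g@value_source,
        created_at = format(g@created_at, "%Y-%m-%dT%H:%M:%OS3%z"),
        input_count = g@input_count, output_count = g@output_count,
        input_barcodes = g@input_barcodes,
        output_barcodes = g@output_barcodes))
    )
    jsonlite::write_json(audit, audit_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(scheme_path)) {
    write_scheme(chain_to_scheme(chain), scheme_path)
  }
  invisible(list(audit = audit_path, scheme = scheme_path))
}

#' Turn a chain into an in-memory replayable scheme
#' @param chain a [GateChain-class].
#' @return a `gating_scheme` list (schema_version, name, normalization,
#'   gates without barcodes).
#' @export
chain_to_scheme <- function(chain) {
  structure(list(
    schema_version = scheme_schema_version,
    name = chain@name,
    normalization = chain@normalization,
    gates = lapply(chain@gates, function(g) list(
      label = g@label,
      assay_x = g@assay_x, feature_x = g@feature_x,
      assay_y = g@assay_y, feature_y = g@feature_y,
      geometry = geometry_to_list(gate_geometry_of(g))))
  ), class = "gating_scheme")
}

#' Build a gating scheme from gate specifications
#'
#' @param name scheme name.
#' @param gates list of gate specs, each a list with `label`, `assay_x`,
#'   `feature_x`, `assay_y`, `feature_y` and a `gate_geometry` under
#'   `geometry`.
#' @param normalization optional normalization record to embed.
#' @return a `gating_scheme`.
#' @export
gating_scheme <- function(name, gates, normalization = list()) {
  gates <- lapply(gates, function(g) {
    for (k in c("label", "assay_x", "feature_x", "assay_y", "feature_y",
                "geometry")) {
      if (is.null(g[[k]])) stop_fmt("gate spec lacking required key '%s'", k)
    }
    if (inherits(g$geometry, "gate_geometry")) {
      g$geometry <- geometry_to_list(g$geometry)
    }
    g[c("label", "assay_x", "feature_x", "assay_y", "feature_y", "geometry")]
  })
  structure(list(schema_version = scheme_schema_version, name = name,
                 normalization = normalization, gates = gates),
            class = "gating_scheme")
}

#' Write a gating scheme to YAML
#' @param scheme a `gating_scheme`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  # gate coordinates must survive the round trip bit-exactly (replay is
  # required to reproduce every output count): emit doubles with 17
  # significant digits, which uniquely identifies a double
  yaml::write_yaml(unclass(scheme), path, handlers = list(
    numeric = function(v) structure(fmt_full(v), class = "verbatim")))
  invisible(path)
}

#' Read a gating scheme from YAML
#'
#' Validates the schema version and the presence of every required gate key;
#' a malformed scheme fails with an error naming the missing key.
#'
#' @param path scheme YAML file.
#' @return a `gating_scheme`.
#' @export
import_scheme <- function(path) {
  if (!file.exists(path)) stop_fmt("scheme file not found: '%s'", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version)) {
    stop_fmt("scheme lacking required key 'schema_version'")
  }
  if (!identical(as.character(raw$schema_version), scheme_schema_version)) {
    stop_fmt("scheme schema version mismatch: found '%s', expected '%s'",
             raw$schema_version, scheme_schema_version)
  }
  if (is.null(raw$gates)) stop_fmt("scheme lacking required key 'gates'")
  scheme <- gating_scheme(
    name = if (is.null(raw$name)) "scheme" else raw$name,
    gates = raw$gates,
    normalization = if (is.null(raw$normalization)) list() else raw$normalization)
  # construction validates every geometry
  for (g in scheme$gates) geometry_from_list(g$geometry)
  scheme
}

#' Replay a gating scheme on a container
#'
#' Deterministically re-applies every gate of a scheme in order, starting
#' from the full cell set (or a supplied root). All features are resolved
#' before any gate runs, so a missing feature fails pre-flight rather than
#' mid-chain. A normalization record mismatch between scheme and container
#' warns: the replay is still exact, but the values being gated were produced
#' differently.
#'
#' @param scheme a `gating_scheme` (in memory or via [import_scheme()]).
#' @param container an [OmicsContainer-class] with the scheme's features.
#' @param root_barcodes cells the first gate draws from (default: all).
#' @param value_source forwarded to [apply_gate()].
#' @return a [GateChain-class].
#' @export
replay <- function(scheme, container, root_barcodes = container@barcodes,
                   value_source = "normalized") {
  stopifnot(inherits(scheme, "gating_scheme"))
  for (g in scheme$gates) {
    resolve_feature(container, g$assay_x, g$feature_x)
    resolve_feature(container, g$assay_y, g$feature_y)
  }
  if (length(scheme$normalization) && length(container@norm_record) &&
      !identical(lapply(scheme$normalization, as.character),
                 lapply(container@norm_record, as.character))) {
    warn_fmt("scheme and container normalization records differ")
  }
  chain <- gate_chain(container, name = scheme$name)
  chain@root_barcodes <- container@barcodes[container@barcodes %in% root_barcodes]
  frontier <- chain@root_barcodes
  for (g in scheme$gates) {
    gate <- apply_gate(container, g$label, g$assay_x, g$feature_x,
                       g$assay_y, g$feature_y,
                       geometry_from_list(g$geometry),
                       input_barcodes = frontier,
                       value_source = value_source)
    chain <- chain_append(chain, gate)
    frontier <- gate@output_barcodes
  }
  chain
}
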