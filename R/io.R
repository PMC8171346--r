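#' Read a (multi-model) PDB file into a StructureEnsemble
#'
#' Multi-model PDB is the trajectory interchange format of this package: one
#' frame == one MODEL record. Parsing is delegated to \pkg{bio3d}; a pre-scan
#' enforces that every MODEL carries the same atom roster and names the
#' offending model otherwise.
#'
#' @param path PDB file path.
#' @param model_selection `"all"` (default) or an integer vector of model
#'   indices to keep, in file order.
#' @param chain optional single chain identifier to select.
#' @return A [structure_ensemble()].
#' @export
read_ensemble <- function(path, model_selection = "all", chain = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grepl("^MODEL ", lines)
  if (any(model_starts)) {
    model_id <- cumsum(model_starts)
    counts <- table(model_id[is_atom])
    if (length(unique(as.integer(counts))) > 1L) {
      bad <- names(counts)[as.integer(counts) != as.integer(counts)[1]][1]
      stop_("inconsistent atom count across models: model %s has %s atoms, model %s has %s",
            bad, counts[[bad]], names(counts)[1], counts[[1]])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom[, c("eleno", "elety", "resid", "chain", "resno")]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!is.null(chain)) {
    idx <- which(atoms$chain == chain)
    if (!length(idx)) stop_("no atoms on chain %s", chain)
    atoms <- atoms[idx, , drop = FALSE]
    xyz <- xyz[, xyz_indices(idx), drop = FALSE]
  }
  if (!identical(model_selection, "all")) {
    sel <- as.integer(model_selection)
    if (any(sel < 1 | sel > nrow(xyz))) {
      stop_("model selection out of range 1..%d", nrow(xyz))
    }
    xyz <- xyz[sel, , drop = FALSE]
  }
  structure_ensemble(atoms, xyz)
}

#' Write a StructureEnsemble as a multi-model PDB file
#'
#' Round-trips with [read_ensemble()] to full stored (PDB fixed-point)
#' precision, i.e. 0.001 Angstrom.
#'
#' @param ens a `StructureEnsemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  bio3d::write.pdb(
    file = path, xyz = ens$xyz,
    resno = ens$atoms$resno, resid = ens$atoms$resid,
    elety = ens$atoms$elety, chain = ens$atoms$chain,
    eleno = ens$atoms$eleno
  )
  invisible(path)
}

#' Declare the expected layout of a delimited table
#'
#' @param columns character vector of required column names.
#' @param units named character vector documenting units per numeric column.
#' @param sentinel missing-value token (never coerced to a number).
#' @return A `TableSpec` list.
#' @export
table_spec <- function(columns, units = character(), sentinel = "NA") {
  stopifnot(is.character(columns), length(columns) >= 1)
  structure(list(columns = columns, units = units, sentinel = sentinel),
            class = "TableSpec")
}

#' Read a delimited table against a TableSpec
#'
#' The header must contain every column the spec requires; the sentinel is
#' mapped to `NA`, never to zero.
#'
#' @param path CSV file path (comma-separated, header row).
#' @param spec a [table_spec()].
#' @return data.frame with the spec's columns.
#' @export
read_table_spec <- function(path, spec) {
  stopifnot(inherits(spec, "TableSpec"))
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.csv(path, na.strings = spec$sentinel,
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(spec$columns, names(df))
  if (length(missing)) {
    stop_("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  message(sprintf("read %d rows from %s", nrow(df), path))
  df[, spec$columns, drop = FALSE]
}

#' Read a structured run configuration (YAML)
#'
#' A run configuration names the pipeline stage, its inputs, a flat or nested
#' parameter map, a seed, and an output directory. Unknown top-level keys are
#' rejected; a seed is mandatory whenever `requires_seed` is `TRUE`.
#'
#' @param path YAML file path.
#' @param requires_seed must a seed be present? Default `TRUE`.
#' @return list with elements `stage`, `inputs`, `parameters`, `seed`, `outdir`.
#' @export
read_run_config <- function(path, requires_seed = TRUE) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("stage", "inputs", "parameters", "seed", "outdir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop_("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$stage)) stop_("config must name a stage")
  if (requires_seed && is.null(cfg$seed)) {
    stop_("config must provide a seed (stage may sample randomness)")
  }
  cfg$inputs <- cfg$inputs %||% list()
  cfg$parameters <- cfg$parameters %||% list()
  cfg$outdir <- cfg$outdir %||% "."
  cfg
}
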