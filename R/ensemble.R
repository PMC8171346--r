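#' Structure ensembles
#'
#' A `StructureEnsemble` holds an ordered set of conformational models (NMR
#' models or trajectory frames) sharing one atom roster. Coordinates are in
#' Angstroms and residue numbers are the author-assigned numbers from the
#' source file (cTnC 1-161); no renumbering is ever applied.
#'
#' @param atoms data.frame with columns `eleno`, `elety` (atom name, e.g.
#'   `"CA"`), `resid` (three-letter residue name), `chain`, `resno`.
#' @param xyz numeric matrix, one row per model, `3 * natoms` columns in
#'   x1,y1,z1,x2,... order (the bio3d convention).
#' @param truth optional named list of generator ground-truth parameters.
#' @return An object of class `StructureEnsemble`.
#' @export
structure_ensemble <- function(atoms, xyz, truth = NULL) {
  req <- c("eleno", "elety", "resid", "chain", "resno")
  if (!all(req %in% names(atoms))) {
    stop_("atoms must have columns: %s", paste(req, collapse = ", "))
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop_("xyz has %d columns but atoms imply %d", ncol(xyz), 3L * nrow(atoms))
  }
  structure(
    list(atoms = as.data.frame(atoms), xyz = unname(as.matrix(xyz)),
         truth = truth),
    class = "StructureEnsemble"
  )
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf("StructureEnsemble: %d model(s), %d atoms, residues %d-%d\n",
              n_models(x), n_atoms(x), min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Number of models / atoms in an ensemble
#' @param ens a `StructureEnsemble`
#' @return integer count
#' @export
n_models <- function(ens) nrow(ens$xyz)

#' @rdname n_models
#' @export
n_atoms <- function(ens) nrow(ens$atoms)

#' Extract one model's coordinates as an N x 3 matrix
#' @param ens a `StructureEnsemble`
#' @param i model index
#' @return numeric matrix with columns x, y, z (Angstrom)
#' @export
model_coords <- function(ens, i = 1L) {
  stopifnot(i >= 1, i <= n_models(ens))
  matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# Atom-roster indices matching the given selection (any arg NULL = no filter).
atom_indices <- function(ens, resno = NULL, elety = NULL, heavy_only = FALSE) {
  keep <- rep(TRUE, n_atoms(ens))
  if (!is.null(resno)) keep <- keep & ens$atoms$resno %in% resno
  if (!is.null(elety)) keep <- keep & ens$atoms$elety %in% elety
  if (heavy_only) keep <- keep & !grepl("^H|^[0-9]H", ens$atoms$elety)
  which(keep)
}

# Expand atom indices to xyz column indices.
xyz_indices <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

# Calpha coordinates of selected residues for one model, erroring with the
# list of residues whose CA is missing.
calpha_coords <- function(ens, model, resno) {
  idx <- atom_indices(ens, resno = resno, elety = "CA")
  found <- ens$atoms$resno[idx]
  missing <- setdiff(resno, found)
  if (length(missing)) {
    stop_("missing Calpha for residue(s): %s", paste(missing, collapse = ", "))
  }
  idx <- idx[order(ens$atoms$resno[idx])]
  model_coords(ens, model)[idx, , drop = FALSE]
}
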