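#' Helix-range specification for interhelical angles
#'
#' Defaults are the cTnC helix-A and helix-B Calpha ranges (residues 14-25
#' and 38-47, author numbering).
#'
#' @param helix_a,helix_b inclusive residue-number ranges (>= 4 residues,
#'   disjoint).
#' @return A `HelixSpec` list.
#' @export
helix_spec <- function(helix_a = 14:25, helix_b = 38:47) {
  if (length(helix_a) < 4 || length(helix_b) < 4) stop_("each helix needs >= 4 residues")
  if (length(intersect(helix_a, helix_b))) stop_("helix ranges must be disjoint")
  structure(list(helix_a = helix_a, helix_b = helix_b), class = "HelixSpec")
}

#' Axis of a helix from its Calpha trace
#'
#' Local axis directions are built from the bisector construction: at each
#' interior Calpha the bisector of the two chain bonds points radially
#' toward the helix axis, and the cross product of consecutive bisectors is
#' parallel to the axis (exactly so for an ideal helix, which a principal
#' direction of the raw Calpha cloud is not at helix lengths of 10-12
#' residues). The axis is the first principal direction (SVD) of these
#' local estimates, oriented N->C: the projection of (last Calpha - first
#' Calpha) onto the axis is made positive.
#'
#' @param coords ordered N x 3 Calpha coordinate matrix (Angstrom).
#' @return list with unit `axis` (length-3) and `centroid`.
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) stop_("need >= 4 Calpha positions to define a helix axis")
  # bisectors at interior residues (radial, pointing toward the axis)
  b <- t(vapply(2:(n - 1), function(i) {
    v <- (coords[i - 1, ] - coords[i, ]) + (coords[i + 1, ] - coords[i, ])
    v
  }, numeric(3)))
  locals <- t(vapply(seq_len(nrow(b) - 1), function(k) {
    v <- c(b[k, 2] * b[k + 1, 3] - b[k, 3] * b[k + 1, 2],
           b[k, 3] * b[k + 1, 1] - b[k, 1] * b[k + 1, 3],
           b[k, 1] * b[k + 1, 2] - b[k, 2] * b[k + 1, 1])
    v
  }, numeric(3)))
  norms <- sqrt(rowSums(locals^2))
  ok <- norms > 1e-9
  if (!any(ok)) stop_("degenerate (collinear) Calpha trace: no helix axis")
  locals <- locals[ok, , drop = FALSE] / norms[ok]
  sv <- svd(locals)
  axis <- sv$v[, 1]
  if (sum(axis * colMeans(locals)) < 0) axis <- -axis
  span <- coords[n, ] - coords[1, ]
  if (sum(axis * span) < 0) axis <- -axis
  list(axis = axis, centroid = colMeans(coords))
}

#' AB interhelical angle of each model in an ensemble
#'
#' Angle (degrees, in `[0, 180]`) between the oriented principal axes of the
#' two helix Calpha traces. Because the axes are N->C oriented, parallel and
#' antiparallel packings are distinguished.
#'
#' @param ens a `StructureEnsemble`.
#' @param spec a [helix_spec()] (default: cTnC helices A and B).
#' @return numeric vector, one angle per model.
#' @export
ab_angle <- function(ens, spec = helix_spec()) {
  stopifnot(inherits(ens, "StructureEnsemble"))
  vapply(seq_len(n_models(ens)), function(m) {
    a <- helix_axis(calpha_coords(ens, m, spec$helix_a))$axis
    b <- helix_axis(calpha_coords(ens, m, spec$helix_b))$axis
    cosang <- max(-1, min(1, sum(a * b)))
    acos(cosang) * 180 / pi
  }, numeric(1))
}

#' Open-state fraction of an angle ensemble
#'
#' Fraction of models with interhelical angle strictly below the threshold
#' (default 110 degrees), with a seeded bootstrap confidence interval over
#' models and, when replicate labels are given, per-replicate fractions.
#'
#' @param angles per-model angles in degrees.
#' @param threshold open-state cut (strict `<`), default 110.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param replicate optional replicate label per angle.
#' @param conf confidence level (default 0.95).
#' @return list: `fraction`, `ci` (percentile bootstrap), `per_replicate`.
#' @export
open_fraction <- function(angles, threshold = 110, n_boot = 1000, seed = 1,
                          replicate = NULL, conf = 0.95) {
  if (!length(angles)) stop_("need at least one angle")
  open <- angles < threshold
  frac <- mean(open)
  ci <- with_seed(seed, {
    bs <- vapply(seq_len(n_boot), function(i) {
      mean(open[sample.int(length(open), replace = TRUE)])
    }, numeric(1))
    stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  per_rep <- if (!is.null(replicate)) {
    tapply(open, replicate, mean)
  } else NULL
  list(fraction = frac, ci = ci, per_replicate = per_rep,
       threshold = threshold)
}

# Least-squares (Kabsch) superposition of every model onto model 1 using the
# given atom indices; returns the aligned xyz matrix.
align_ensemble <- function(ens, align_idx) {
  if (!length(align_idx)) stop_("alignment selection is empty")
  bio3d::fit.xyz(fixed = ens$xyz[1, ], mobile = ens$xyz,
                 fixed.inds = xyz_indices(align_idx),
                 mobile.inds = xyz_indices(align_idx))
}

#' Per-residue RMSF after backbone superposition
#'
#' All models are first least-squares superposed onto model 1 using the
#' backbone atoms (N, CA, C, O) of the alignment residue range (default
#' cTnC 1-100); RMSF is then computed over Calpha atoms.
#'
#' @param ens a `StructureEnsemble` with >= 2 models.
#' @param align_resno residues used for superposition (default 1:100).
#' @return data.frame (resno, rmsf) in Angstrom.
#' @export
rmsf <- function(ens, align_resno = 1:100) {
  stopifnot(inherits(ens, "StructureEnsemble"))
  if (n_models(ens) < 2) stop_("RMSF needs >= 2 models")
  bb <- atom_indices(ens, resno = align_resno,
                     elety = c("N", "CA", "C", "O"))
  xyz <- align_ensemble(ens, bb)
  ca <- atom_indices(ens, elety = "CA")
  out <- vapply(ca, function(i) {
    pos <- xyz[, xyz_indices(i), drop = FALSE]
    mu <- colMeans(pos)
    sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
  }, numeric(1))
  data.frame(resno = ens$atoms$resno[ca], rmsf = out)
}

contact_modes <- list(
  "heavy-7" = list(atoms = "heavy", cutoff = 7, min_sep = 6),
  "calpha-5" = list(atoms = "calpha", cutoff = 5, min_sep = 3)
)

#' Residue-residue contact map
#'
#' Two definitions are supported: `"heavy-7"` (any heavy-atom pair within
#' 7 Angstrom, residues separated by at least 6 in sequence) and
#' `"calpha-5"` (Calpha pair within 5 Angstrom, minimum separation 3 to
#' exclude trivial chain neighbours). For an ensemble the per-pair occupancy
#' over models is reported alongside the union contact list.
#'
#' @param ens a `StructureEnsemble` (one or more models).
#' @param mode `"heavy-7"` or `"calpha-5"`.
#' @return A `ContactMap`: data.frame (i, j, dist, occupancy) plus
#'   definition metadata in attributes.
#' @export
contact_map <- function(ens, mode = c("heavy-7", "calpha-5")) {
  mode <- match.arg(mode)
  def <- contact_modes[[mode]]
  idx <- if (def$atoms == "calpha") atom_indices(ens, elety = "CA")
         else atom_indices(ens, heavy_only = TRUE)
  if (!length(idx)) stop_("no atoms of the selected class present")
  resno <- ens$atoms$resno[idx]
  maps <- lapply(seq_len(n_models(ens)), function(m) {
    coords <- model_coords(ens, m)[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(coords))
    # residue-pair minimum distance
    pairs <- which(upper.tri(D) & D <= def$cutoff, arr.ind = TRUE)
    if (!nrow(pairs)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
    ri <- resno[pairs[, 1]]; rj <- resno[pairs[, 2]]
    lo <- pmin(ri, rj); hi <- pmax(ri, rj)
    keep <- (hi - lo) >= def$min_sep
    if (!any(keep)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
    d <- D[pairs][keep]
    key <- paste(lo[keep], hi[keep])
    mind <- tapply(d, key, min)
    ij <- do.call(rbind, strsplit(names(mind), " "))
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
               dist = as.numeric(mind))
  })
  all_keys <- unique(unlist(lapply(maps, function(m) paste(m$i, m$j))))
  occ <- vapply(all_keys, function(k) {
    mean(vapply(maps, function(m) k %in% paste(m$i, m$j), logical(1)))
  }, numeric(1))
  mind <- vapply(all_keys, function(k) {
    min(unlist(lapply(maps, function(m) m$dist[paste(m$i, m$j) == k])), na.rm = TRUE)
  }, numeric(1))
  ij <- do.call(rbind, strsplit(all_keys, " "))
  out <- if (length(all_keys)) {
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
               dist = unname(mind), occupancy = unname(occ))
  } else data.frame(i = integer(), j = integer(), dist = numeric(),
                    occupancy = numeric())
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mode = mode, cutoff = def$cutoff, min_sep = def$min_sep,
            class = c("ContactMap", "data.frame"))
}

#' Difference between two contact maps
#'
#' Set algebra on (i, j) residue pairs of two maps computed under the same
#' definition; occupancy deltas are reported for persistent pairs.
#'
#' @param mapA,mapB `ContactMap`s with identical definitions.
#' @return list with data.frames `gained` (in B only), `lost` (in A only),
#'   `persistent` (with `d_occupancy` = B - A).
#' @export
diff_contact_map <- function(mapA, mapB) {
  if (!identical(attr(mapA, "mode"), attr(mapB, "mode"))) {
    stop_("contact definitions differ: %s vs %s",
          attr(mapA, "mode"), attr(mapB, "mode"))
  }
  ka <- paste(mapA$i, mapA$j); kb <- paste(mapB$i, mapB$j)
  gained <- mapB[!(kb %in% ka), c("i", "j"), drop = FALSE]
  lost <- mapA[!(ka %in% kb), c("i", "j"), drop = FALSE]
  common <- intersect(ka, kb)
  persistent <- mapA[ka %in% common, c("i", "j"), drop = FALSE]
  persistent$d_occupancy <- mapB$occupancy[match(common, kb)] -
    mapA$occupancy[match(common, ka)]
  rownames(gained) <- rownames(lost) <- rownames(persistent) <- NULL
  list(gained = gained, lost = lost, persistent = persistent)
}

#' Calpha principal component analysis of an ensemble
#'
#' Models are superposed onto model 1 (Kabsch, using the analysis selection
#' itself) and the covariance of the selected Calpha coordinates is
#' eigen-decomposed. The default selection is the cTnC core region,
#' residues 4-85.
#'
#' @param ens a `StructureEnsemble` with >= 3 models.
#' @param resno residue selection (default 4:85).
#' @return A `PCAResult`: `mean` structure, `rotation` (eigenvectors),
#'   `eigenvalues` (Angstrom^2), `projections` (centered scores),
#'   `variance_fraction`.
#' @export
pca_ensemble <- function(ens, resno = 4:85) {
  stopifnot(inherits(ens, "StructureEnsemble"))
  if (n_models(ens) < 3) stop_("PCA needs >= 3 models")
  ca <- atom_indices(ens, resno = resno, elety = "CA")
  if (!length(ca)) stop_("no Calpha atoms in the selection")
  xyz <- align_ensemble(ens, ca)
  X <- xyz[, xyz_indices(ca), drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(mean = mu, rotation = pc$rotation, eigenvalues = ev,
                 projections = pc$x,
                 variance_fraction = ev / sum(ev),
                 resno = sort(unique(ens$atoms$resno[ca]))),
            class = "PCAResult")
}

#' One-dimensional free-energy landscape from PC projections
#'
#' Boltzmann inversion of the binned PC1 density: dG(bin) =
#' -ln(count / max count) in kT units; empty bins are masked (`NA`), never
#' assigned zero energy.
#'
#' @param projections PC1 values.
#' @param bins number of bins (>= 2; default 50).
#' @param temperature temperature in K (annotation only; dG is in kT).
#' @return data.frame (center, count, dG_kT) with the populated minimum at 0.
#' @export
fel_1d <- function(projections, bins = 50, temperature = 310) {
  if (bins < 2) stop_("need at least 2 bins")
  if (length(projections) < 50) {
    warn_("fewer than 50 samples; free-energy landscape will be noisy")
  }
  h <- graphics::hist(projections, breaks = bins, plot = FALSE)
  counts <- h$counts
  dg <- ifelse(counts > 0, -log(counts / max(counts)), NA_real_)
  structure(data.frame(center = h$mids, count = counts, dG_kT = dg),
            temperature_K = temperature)
}

#' Welch two-sample t test with a degenerate-case convention
#'
#' Two-sided Welch test of per-replicate fractions (or any two groups).
#' When both groups have zero variance and equal means, p = 1 by convention.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @return list with `t` and `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) stop_("need >= 2 values per group")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1))
    stop_("zero variance in both groups with unequal means: t undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
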