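#' Statistical contact potentials
#'
#' A `StatPotential` is a symmetric 20x20 matrix of residue-pair contact
#' energies (dimensionless, lower = more favorable) indexed by one-letter
#' amino-acid codes. Any such matrix is accepted by the frustration
#' calculators; [default_potential()] ships a simplified
#' hydrophobicity-transfer potential in which pairing two hydrophobic
#' residues is most favorable, the dominant signal of knowledge-based
#' contact potentials.
#'
#' @param energies 20x20 symmetric numeric matrix with one-letter AA
#'   dimnames.
#' @param name provenance tag.
#' @return A `StatPotential`.
#' @export
stat_potential <- function(energies, name = "custom") {
  aa <- sort(unname(AA3TO1))
  energies <- as.matrix(energies)
  if (!all(dim(energies) == c(20, 20)) ||
      !setequal(rownames(energies), aa) || !setequal(colnames(energies), aa)) {
    stop_("potential must be 20x20 with one-letter amino-acid dimnames")
  }
  energies <- energies[aa, aa]
  if (any(abs(energies - t(energies)) > 1e-12)) stop_("potential must be symmetric")
  if (any(!is.finite(energies))) stop_("all 400 entries must be finite")
  structure(list(E = energies, name = name), class = "StatPotential")
}

# Kyte-Doolittle hydropathy, used to build the default contact potential.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' @rdname stat_potential
#' @export
default_potential <- function() {
  aa <- sort(names(KD_HYDROPATHY))
  h <- KD_HYDROPATHY[aa]
  E <- -outer(h, h, `+`) / 4
  stat_potential(E, name = "hydrophobicity-transfer")
}

# residue-number -> one-letter code map for a structure, with validation
chain_sequence <- function(ens) {
  ca <- atom_indices(ens, elety = "CA")
  resno <- ens$atoms$resno[ca]
  code <- aa_three_to_one(ens$atoms$resid[ca])
  bad <- unique(ens$atoms$resid[ca][is.na(code)])
  if (length(bad)) {
    stop_("no potential entry for nonstandard residue(s): %s",
          paste(bad, collapse = ", "))
  }
  stats::setNames(code, resno)
}

#' Native contact energies
#'
#' Looks up the potential energy of each contact pair's native residue
#' identities.
#'
#' @param ens a `StructureEnsemble`.
#' @param potential a [stat_potential()].
#' @param contacts a [contact_map()] (computed if omitted).
#' @param contact_mode mode used when `contacts` is omitted.
#' @return the contact data.frame with an `E_native` column.
#' @export
native_contact_energy <- function(ens, potential = default_potential(),
                                  contacts = NULL, contact_mode = "calpha-5") {
  stopifnot(inherits(potential, "StatPotential"))
  if (is.null(contacts)) contacts <- contact_map(ens, mode = contact_mode)
  seqmap <- chain_sequence(ens)
  ai <- seqmap[as.character(contacts$i)]
  aj <- seqmap[as.character(contacts$j)]
  contacts$E_native <- potential$E[cbind(ai, aj)]
  contacts
}

#' Local mutational frustration index of one contact
#'
#' Measures how favorable the native contact is relative to a set of decoy
#' interactions: both residue identities are independently resampled from
#' the chain's residue composition, and
#' F = (mean(E_decoy) - E_native) / SD(E_decoy). Positive F means the
#' native pair is more favorable than typical decoys (minimally
#' frustrated); strongly negative F marks a highly frustrated contact.
#' As a z-score, F is invariant under affine rescaling of the potential.
#'
#' @param ens a `StructureEnsemble`.
#' @param pair `c(i, j)` residue numbers of a contact.
#' @param potential a [stat_potential()].
#' @param n_decoys decoy count (>= 100; default 1000).
#' @param seed RNG seed.
#' @param composition optional character vector of one-letter codes to
#'   resample from (defaults to the chain's own composition).
#' @return the scalar index F.
#' @export
mutational_frustration_index <- function(ens, pair,
                                         potential = default_potential(),
                                         n_decoys = 1000, seed = 1,
                                         composition = NULL) {
  if (n_decoys < 100) stop_("n_decoys must be >= 100")
  seqmap <- chain_sequence(ens)
  comp <- composition %||% unname(seqmap)
  e_nat <- potential$E[seqmap[as.character(pair[1])], seqmap[as.character(pair[2])]]
  with_seed(seed, {
    di <- sample(comp, n_decoys, replace = TRUE)
    dj <- sample(comp, n_decoys, replace = TRUE)
    e_dec <- potential$E[cbind(di, dj)]
    s <- stats::sd(e_dec)
    if (s == 0) stop_("degenerate decoy distribution (SD = 0)")
    (mean(e_dec) - e_nat) / s
  })
}

#' Three-way frustration classification
#'
#' @param F frustration index (finite).
#' @param hi_cut minimal-frustration cut: `F >= hi_cut` is `"minimal"`
#'   (default 0.78, the conventional cut of published frustration scans).
#' @param lo_cut high-frustration cut: `F <= lo_cut` is `"high"`
#'   (default -1.0).
#' @return `"minimal"`, `"neutral"` or `"high"` (vectorized).
#' @export
classify_frustration <- function(F, hi_cut = 0.78, lo_cut = -1.0) {
  if (hi_cut <= lo_cut) stop_("hi_cut must exceed lo_cut")
  if (any(!is.finite(F))) stop_("frustration index must be finite")
  ifelse(F >= hi_cut, "minimal", ifelse(F <= lo_cut, "high", "neutral"))
}

#' Full per-contact frustration map of a structure
#'
#' @param ens a `StructureEnsemble`.
#' @param potential a [stat_potential()].
#' @param contact_mode contact definition (see [contact_map()]).
#' @param n_decoys decoys per contact.
#' @param seed RNG seed (the map is bit-reproducible under a fixed seed).
#' @param hi_cut,lo_cut classification cuts (see [classify_frustration()]).
#' @return A `FrustrationMap` data.frame: i, j, dist, E_native, decoy_mean,
#'   decoy_sd, F, class.
#' @export
frustration_map <- function(ens, potential = default_potential(),
                            contact_mode = "calpha-5", n_decoys = 1000,
                            seed = 1, hi_cut = 0.78, lo_cut = -1.0) {
  contacts <- native_contact_energy(ens, potential, contact_mode = contact_mode)
  if (!nrow(contacts)) {
    out <- cbind(contacts, decoy_mean = numeric(0), decoy_sd = numeric(0),
                 F = numeric(0), class = character(0))
    return(structure(out, mode = attr(contacts, "mode"),
                     class = c("FrustrationMap", "data.frame")))
  }
  seqmap <- chain_sequence(ens)
  comp <- unname(seqmap)
  res <- with_seed(seed, {
    t(vapply(seq_len(nrow(contacts)), function(k) {
      di <- sample(comp, n_decoys, replace = TRUE)
      dj <- sample(comp, n_decoys, replace = TRUE)
      e_dec <- potential$E[cbind(di, dj)]
      c(mean(e_dec), stats::sd(e_dec))
    }, numeric(2)))
  })
  if (any(res[, 2] == 0)) stop_("degenerate decoy distribution (SD = 0)")
  contacts$decoy_mean <- res[, 1]
  contacts$decoy_sd <- res[, 2]
  contacts$F <- (contacts$decoy_mean - contacts$E_native) / contacts$decoy_sd
  contacts$class <- classify_frustration(contacts$F, hi_cut, lo_cut)
  structure(contacts, mode = attr(contacts, "mode"),
            class = c("FrustrationMap", "data.frame"))
}

#' Compare frustration maps across conformational states
#'
#' Aligns per-contact classes across labeled maps (e.g. closed / primed /
#' open) and tabulates transitions; contacts absent from a state are
#' labeled `"absent"`.
#'
#' @param maps named list of `FrustrationMap`s sharing one contact
#'   definition.
#' @return list: `table` (pair x state class data.frame with a `transition`
#'   string) and `counts` (table of transition patterns).
#' @export
compare_states <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 2, !is.null(names(maps)))
  modes <- vapply(maps, function(m) attr(m, "mode"), character(1))
  if (length(unique(modes)) != 1) {
    stop_("maps use different contact definitions: %s",
          paste(unique(modes), collapse = ", "))
  }
  keys <- unique(unlist(lapply(maps, function(m) paste(m$i, m$j))))
  classes <- vapply(maps, function(m) {
    k <- paste(m$i, m$j)
    out <- rep("absent", length(keys))
    hit <- match(keys, k)
    out[!is.na(hit)] <- m$class[hit[!is.na(hit)]]
    out
  }, character(length(keys)))
  classes <- matrix(classes, nrow = length(keys),
                    dimnames = list(keys, names(maps)))
  ij <- do.call(rbind, strsplit(keys, " "))
  tab <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    classes, check.names = FALSE)
  tab$transition <- apply(classes, 1, paste, collapse = "->")
  list(table = tab[order(tab$i, tab$j), ],
       counts = table(tab$transition))
}
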