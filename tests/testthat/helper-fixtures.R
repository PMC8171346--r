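# Fixtures built in code: toy structures and brute-force oracles.

# Random compact toy structure with varied residue identities (Calpha only).
toy_structure <- function(n_res = 40, seed = 1, step = 2.5) {
  set.seed(seed)
  coords <- apply(matrix(rnorm(n_res * 3, 0, step), ncol = 3), 2, cumsum)
  atoms <- data.frame(
    eleno = seq_len(n_res), elety = "CA",
    resid = sample(names(tnckit:::AA3TO1), n_res, replace = TRUE),
    chain = "A", resno = seq_len(n_res)
  )
  structure_ensemble(atoms, as.vector(t(coords)))
}

# Toy structure with two heavy atoms (CA + CB) per residue.
toy_structure_heavy <- function(n_res = 25, seed = 2) {
  set.seed(seed)
  ca <- apply(matrix(rnorm(n_res * 3, 0, 2.2), ncol = 3), 2, cumsum)
  cb <- ca + matrix(rnorm(n_res * 3, 0, 1), ncol = 3)
  atoms <- data.frame(
    eleno = seq_len(2 * n_res), elety = rep(c("CA", "CB"), n_res),
    resid = rep(sample(names(tnckit:::AA3TO1), n_res, replace = TRUE), each = 2),
    chain = "A",
    resno = rep(seq_len(n_res), each = 2)
  )
  coords <- do.call(rbind, lapply(seq_len(n_res), function(i) rbind(ca[i, ], cb[i, ])))
  structure_ensemble(atoms, as.vector(t(coords)))
}

# O(N^2) brute-force contact oracle over residue pairs.
brute_force_contacts <- function(ens, atoms = c("calpha", "heavy"),
                                 cutoff, min_sep, model = 1) {
  atoms <- match.arg(atoms)
  idx <- if (atoms == "calpha") which(ens$atoms$elety == "CA")
         else which(!grepl("^H|^[0-9]H", ens$atoms$elety))
  coords <- model_coords(ens, model)[idx, , drop = FALSE]
  resno <- ens$atoms$resno[idx]
  residues <- sort(unique(resno))
  out <- list()
  for (a in seq_along(residues)) {
    for (b in seq_along(residues)) {
      if (b <= a) next
      i <- residues[a]; j <- residues[b]
      if (j - i < min_sep) next
      ci <- coords[resno == i, , drop = FALSE]
      cj <- coords[resno == j, , drop = FALSE]
      dmin <- Inf
      for (p in seq_len(nrow(ci))) for (q in seq_len(nrow(cj))) {
        dmin <- min(dmin, sqrt(sum((ci[p, ] - cj[q, ])^2)))
      }
      if (dmin <= cutoff) out[[length(out) + 1]] <- data.frame(i = i, j = j, dist = dmin)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  do.call(rbind, out)
}

# toy contact potential over a reduced alphabet, zero elsewhere
toy_potential <- function(entries) {
  aa <- sort(unname(tnckit:::AA3TO1))
  E <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (e in entries) {
    E[e$a, e$b] <- E[e$b, e$a] <- e$E
  }
  stat_potential(E, name = "toy")
}
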