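#' Default relaxation-delay sets
#'
#' Delay lists (seconds) of the R1 and R2 experiments the analyzers expect:
#' 20-1500 ms for R1 and 16-304 ms for R2.
#' @param which `"R1"` or `"R2"`.
#' @return numeric vector of delays in seconds.
#' @export
default_relax_delays <- function(which = c("R1", "R2")) {
  which <- match.arg(which)
  if (which == "R1") c(20, 50, 100, 200, 250, 500, 750, 1000, 1500) / 1000
  else c(16, 48, 80, 112, 144, 176, 208, 240, 272, 304) / 1000
}

#' Default titration ligand concentrations (uM)
#' @return numeric vector including the peptide-free point.
#' @export
default_titration_concs <- function() c(0, 15, 40, 70, 120, 150, 200)

# 1:1 bound fraction from the quadratic binding isotherm.
bound_fraction <- function(L, Pt, Kd) {
  s <- Pt + L + Kd
  (s - sqrt(s^2 - 4 * Pt * L)) / (2 * Pt)
}

#' Generate titration peak lists with 1:1 binding
#'
#' Per-residue chemical-shift displacements follow the quadratic 1:1
#' bound-fraction isotherm scaled by `CSPmax`. The total displacement is
#' split between 1H and 15N as dH = sqrt(0.7) * d and dN = sqrt(3) * d so
#' that the CSP combination sqrt(dH^2 + 0.1 dN^2) recovers the total
#' exactly (the per-nucleus split is a generator convention, not data).
#'
#' @param Kd dissociation constant (uM).
#' @param CSPmax named numeric vector: saturation CSP (ppm) per residue.
#' @param ligand_concs ligand concentrations (uM), must include 0.
#' @param Pt total protein concentration (uM).
#' @param noise Gaussian noise SD on each shift (ppm).
#' @param seed RNG seed.
#' @return list of PeakList data.frames (residue, dH_ppm, dN_ppm, condition),
#'   one per ligand concentration, with attribute `truth`.
#' @export
gen_titration_peaklists <- function(Kd, CSPmax,
                                    ligand_concs = default_titration_concs(),
                                    Pt = 100, noise = 0, seed = 1) {
  if (Pt <= 0) stop_("Pt must be positive")
  if (any(ligand_concs < 0)) stop_("ligand concentrations must be non-negative")
  residues <- as.integer(names(CSPmax) %||% seq_along(CSPmax))
  base_H <- 8.2 + 0.001 * residues
  base_N <- 115 + 0.05 * residues
  with_seed(seed, {
    out <- lapply(ligand_concs, function(L) {
      fb <- if (L == 0) 0 else bound_fraction(L, Pt, Kd)
      d <- unname(CSPmax) * fb
      data.frame(
        residue = residues,
        dH_ppm = base_H + sqrt(0.7) * d + stats::rnorm(length(d), 0, noise),
        dN_ppm = base_N + sqrt(3) * d + stats::rnorm(length(d), 0, noise),
        condition = L
      )
    })
    names(out) <- as.character(ligand_concs)
    attr(out, "truth") <- list(Kd = Kd, CSPmax = CSPmax, Pt = Pt)
    out
  })
}

#' Generate mono-exponential relaxation decays
#'
#' Intensities I0 * exp(-R * t) * (1 + eps) per residue, eps ~ N(0, noise).
#'
#' @param rates named numeric vector of relaxation rates (1/s) per residue.
#' @param delays relaxation delays in seconds.
#' @param noise fractional intensity noise SD.
#' @param seed RNG seed.
#' @param I0 reference intensity (arbitrary units).
#' @return data.frame (residue, delay_s, intensity) with attribute `truth`.
#' @export
gen_relaxation_decays <- function(rates, delays = default_relax_delays("R1"),
                                  noise = 0, seed = 1, I0 = 1e5) {
  if (any(delays <= 0)) stop_("delays must be positive")
  residues <- names(rates) %||% as.character(seq_along(rates))
  with_seed(seed, {
    grid <- expand.grid(residue = residues, delay_s = delays,
                        stringsAsFactors = FALSE)
    mu <- I0 * exp(-rates[grid$residue] * grid$delay_s)
    grid$intensity <- mu * (1 + stats::rnorm(nrow(grid), 0, noise))
    attr(grid, "truth") <- list(rates = rates, I0 = I0)
    grid
  })
}

# Fast-exchange (Luz-Meiboom) dispersion profile.
luz_meiboom <- function(nu, R20, Rex, kex) {
  R20 + Rex * (1 - (4 * nu / kex) * tanh(kex / (4 * nu)))
}

#' Generate CPMG relaxation-dispersion data
#'
#' R2eff(nu) follows the fast-exchange (Luz-Meiboom) closed form
#' R2eff = R20 + Rex * (1 - (4 nu / kex) * tanh(kex / (4 nu))); intensities
#' are back-computed through I_CPMG = I0 * exp(-T * R2eff) so the analyzer's
#' R2eff relation inverts them exactly.
#'
#' @param R20 exchange-free transverse rate (1/s); vector over residues.
#' @param Rex exchange contribution at zero refocusing frequency (1/s).
#' @param kex exchange rate (1/s).
#' @param nu_list CPMG refocusing frequencies (Hz); the default carries the
#'   two canonical points, 50 and 1000 Hz.
#' @param T_relax relaxation period (s).
#' @param noise fractional intensity noise SD.
#' @param seed RNG seed.
#' @return data.frame (residue, nu_hz, I0, intensity, T_s) with `truth`.
#' @export
gen_cpmg <- function(R20, Rex, kex, nu_list = c(50, 1000),
                     T_relax = 0.04, noise = 0, seed = 1) {
  if (T_relax <= 0) stop_("relaxation period must be positive")
  n_res <- max(length(R20), length(Rex))
  R20 <- rep_len(R20, n_res); Rex <- rep_len(Rex, n_res)
  residues <- names(R20) %||% as.character(seq_len(n_res))
  I0 <- 1e5
  with_seed(seed, {
    grid <- expand.grid(residue = seq_len(n_res), nu_hz = nu_list)
    r2 <- luz_meiboom(grid$nu_hz, R20[grid$residue], Rex[grid$residue], kex)
    grid$I0 <- I0
    grid$intensity <- I0 * exp(-T_relax * r2) * (1 + stats::rnorm(nrow(grid), 0, noise))
    grid$T_s <- T_relax
    grid$residue <- residues[grid$residue]
    attr(grid, "truth") <- list(R20 = R20, Rex = Rex, kex = kex)
    grid
  })
}
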