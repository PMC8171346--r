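#' Generate a CD thermal-unfolding curve
#'
#' Sum of one or two two-state sigmoids plus a linear baseline with Gaussian
#' noise: theta(T) = b0 + b1*T + sum_i A_i / (1 + exp((Tm_i - T)/k_i)).
#'
#' @param transitions list of `c(Tm_degC, amplitude, slope_degC)` triples
#'   (1 or 2 transitions).
#' @param baseline `c(intercept, slope)` of the linear baseline.
#' @param T_grid temperature grid in degC (default 20-90 by 0.2, the usual
#'   222 nm thermogram acquisition).
#' @param noise Gaussian noise SD (same units as ellipticity).
#' @param seed RNG seed.
#' @return data.frame (temperature_C, ellipticity) with attribute `truth`.
#' @export
gen_melting_curve <- function(transitions, baseline = c(-2, 0.01),
                              T_grid = seq(20, 90, by = 0.2),
                              noise = 0, seed = 1) {
  if (!length(transitions) %in% 1:2) stop_("1 or 2 transitions supported")
  mu <- baseline[1] + baseline[2] * T_grid
  for (tr in transitions) {
    stopifnot(length(tr) == 3)
    mu <- mu + tr[2] / (1 + exp((tr[1] - T_grid) / tr[3]))
  }
  with_seed(seed, {
    out <- data.frame(temperature_C = T_grid,
                      ellipticity = mu + stats::rnorm(length(T_grid), 0, noise))
    attr(out, "truth") <- list(transitions = transitions, baseline = baseline)
    out
  })
}

# Guinier (compact-globule) and Debye (Gaussian-chain) form factors.
guinier_intensity <- function(s, Rg, I0 = 1) I0 * exp(-(s * Rg)^2 / 3)

debye_intensity <- function(s, Rg, I0 = 1) {
  x <- (s * Rg)^2
  ifelse(x < 1e-12, I0, I0 * 2 * (exp(-x) - 1 + x) / x^2)
}

#' Generate a SAXS profile as a folded/unfolded mixture
#'
#' Mixture of a Guinier compact-globule intensity (bell-shaped Kratky) and a
#' Debye Gaussian-chain intensity (plateau/rising Kratky), weighted by
#' `folded_fraction`.
#'
#' @param Rg radius of gyration of the folded species (Angstrom).
#' @param folded_fraction weight of the folded component in `[0, 1]`.
#' @param s_grid scattering vector grid (1/Angstrom), strictly positive.
#' @param noise fractional intensity noise SD.
#' @param seed RNG seed.
#' @param Rg_unfolded Rg of the unfolded chain (default 1.6 * Rg).
#' @return data.frame (s, I) with attribute `truth`.
#' @export
gen_saxs_profile <- function(Rg = 17, folded_fraction = 1,
                             s_grid = seq(0.006, 0.35, by = 0.002),
                             noise = 0, seed = 1, Rg_unfolded = 1.6 * Rg) {
  if (any(s_grid <= 0)) stop_("s grid must be strictly positive")
  if (folded_fraction < 0 || folded_fraction > 1) stop_("folded_fraction in [0, 1]")
  mu <- folded_fraction * guinier_intensity(s_grid, Rg) +
    (1 - folded_fraction) * debye_intensity(s_grid, Rg_unfolded)
  with_seed(seed, {
    out <- data.frame(s = s_grid,
                      I = mu * (1 + stats::rnorm(length(s_grid), 0, noise)))
    attr(out, "truth") <- list(Rg = Rg, folded_fraction = folded_fraction,
                               Rg_unfolded = Rg_unfolded)
    out
  })
}
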