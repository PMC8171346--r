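#' Default genotype mechanics specifications
#'
#' Ships the per-genotype Hill parameter sets used as study conditions for
#' synthetic force-pCa data: pCa50 5.56 (WT) and 5.72 (C84Y) with a common
#' Hill coefficient, full normalized range, additive noise at S.E.M. scale
#' (SD 0.04) and 6 replicate preparations.
#'
#' @param label `"WT"` or `"C84Y"`.
#' @param pCa50,nHill,Fmax,Fmin,noise_sd,replicates overrides of the default map.
#' @return A `GenotypeMechSpec` list.
#' @export
genotype_mech_spec <- function(label = c("WT", "C84Y"),
                               pCa50 = NULL, nHill = 2.5,
                               Fmax = 1, Fmin = 0,
                               noise_sd = 0.04, replicates = 6) {
  label <- match.arg(label)
  defaults <- c(WT = 5.56, C84Y = 5.72)
  pCa50 <- pCa50 %||% defaults[[label]]
  if (!(Fmax > Fmin) || Fmin < 0) stop_("require Fmax > Fmin >= 0")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  structure(list(label = label, pCa50 = pCa50, nHill = nHill,
                 Fmax = Fmax, Fmin = Fmin, noise_sd = noise_sd,
                 replicates = replicates),
            class = "GenotypeMechSpec")
}

#' Default pCa grid for synthetic titrations
#'
#' Spans pCa 7.0--4.0 with denser sampling around the activation midpoint,
#' the layout of a typical skinned-preparation titration.
#' @return numeric vector of pCa values (decreasing).
#' @export
default_pca_grid <- function() {
  c(7.0, 6.5, 6.2, 6.0, 5.9, 5.8, 5.7, 5.6, 5.5, 5.4, 5.2, 5.0, 4.5, 4.0)
}

#' Generate synthetic force-pCa data for one genotype
#'
#' Draws `replicates x length(grid)` forces from the Hill curve of the spec
#' with additive Gaussian noise; the noiseless curve and the generating
#' parameters are stored in the `truth` attribute.
#'
#' @param spec a [genotype_mech_spec()].
#' @param grid pCa values (must span at least pCa 4.0--7.0).
#' @param seed RNG seed.
#' @return data.frame (pCa, force, genotype, replicate) with attribute `truth`.
#' @export
gen_force_pca <- function(spec, grid = default_pca_grid(), seed = 1) {
  stopifnot(inherits(spec, "GenotypeMechSpec"))
  if (!length(grid)) stop_("empty pCa grid")
  if (min(grid) > 4.0 || max(grid) < 7.0) {
    stop_("grid must span at least [4.0, 7.0] pCa")
  }
  hill <- function(p) spec$Fmin + (spec$Fmax - spec$Fmin) /
    (1 + 10^(spec$nHill * (p - spec$pCa50)))
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(spec$replicates), pCa = grid)
    mu <- hill(rows$pCa)
    force <- mu + stats::rnorm(nrow(rows), 0, spec$noise_sd)
    out <- data.frame(pCa = rows$pCa, force = force,
                      genotype = spec$label, replicate = rows$replicate)
    attr(out, "truth") <- list(spec = spec, curve = data.frame(pCa = sort(grid), force = hill(sort(grid))))
    out
  })
}

#' Generate force and kTR data from the three-state model
#'
#' Evaluates [steady_state()] force and [ktr()] on the grid and applies
#' multiplicative Gaussian noise `(1 + eps)`, `eps ~ N(0, noise)`.
#'
#' @param params a [kinetic_params()].
#' @param grid pCa values.
#' @param noise fractional SD of the multiplicative noise.
#' @param seed RNG seed.
#' @param replicates replicate count (default 6).
#' @return data.frame (pCa, force, ktr, replicate) with attribute `truth`.
#' @export
gen_mechanics_3state <- function(params, grid = default_pca_grid(),
                                 noise = 0.03, seed = 1, replicates = 6) {
  stopifnot(inherits(params, "KineticParams"))
  ss <- steady_state(params, grid)
  kt <- ktr(params, grid, method = "eigen")
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(replicates), idx = seq_along(grid))
    f_mu <- ss$force[rows$idx]
    k_mu <- kt[rows$idx]
    out <- data.frame(
      pCa = grid[rows$idx],
      force = f_mu * (1 + stats::rnorm(nrow(rows), 0, noise)),
      ktr = k_mu * (1 + stats::rnorm(nrow(rows), 0, noise)),
      replicate = rows$replicate
    )
    attr(out, "truth") <- list(params = params,
                               curve = data.frame(pCa = grid, force = ss$force, ktr = kt))
    out
  })
}
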