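#' Interhelical-angle distribution specification
#'
#' Describes a (possibly bimodal) Gaussian mixture of AB interhelical angles
#' for the two-helix ensemble generator.
#'
#' @param components list of `c(mean_deg, sd_deg, weight)` triples; weights
#'   must sum to 1 and means lie in (0, 180) (0 is allowed as the degenerate
#'   parallel case when its SD is 0).
#' @param n_models number of models to generate.
#' @return An `AngleDistSpec` list.
#' @export
angle_dist_spec <- function(components = list(c(110, 5, 0.5), c(150, 5, 0.5)),
                            n_models = 200) {
  comp <- lapply(components, function(x) {
    stopifnot(length(x) == 3)
    c(mean = x[1], sd = x[2], weight = x[3])
  })
  w <- vapply(comp, function(x) x[["weight"]], numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop_("mixture weights must sum to 1")
  m <- vapply(comp, function(x) x[["mean"]], numeric(1))
  if (any(m < 0 | m >= 180)) stop_("component means must lie in [0, 180)")
  if (!is_count(n_models)) stop_("n_models must be a positive integer")
  structure(list(components = comp, n_models = as.integer(n_models)),
            class = "AngleDistSpec")
}

# Ideal alpha-helix Calpha trace along +z: rise 1.5 A/residue, radius 2.3 A,
# 100 degrees twist per residue (textbook values).
ideal_helix_ca <- function(n_res, rise = 1.5, radius = 2.3, twist = 100) {
  i <- seq_len(n_res) - 1
  phi <- i * twist * pi / 180
  cbind(x = radius * cos(phi), y = radius * sin(phi), z = i * rise)
}

rotation_about_y <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), 0, sin(th),
           0, 1, 0,
           -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
}

#' Generate a synthetic two-helix Calpha ensemble with prescribed AB angles
#'
#' Each model contains two ideal alpha-helical Calpha traces labeled with
#' cTnC helix-A residues 14-25 and helix-B residues 38-47. Helix A runs
#' along +z; helix B is rotated so the angle between the oriented N->C axes
#' equals an angle drawn from the mixture in `spec`. The drawn angles are
#' recorded as ground truth in the ensemble's `truth` field.
#'
#' @param spec an [angle_dist_spec()].
#' @param seed RNG seed.
#' @return A `StructureEnsemble`; `$truth$angles` holds the generating angles.
#' @export
gen_two_helix_ensemble <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "AngleDistSpec"))
  res_a <- 14:25
  res_b <- 38:47
  helA <- ideal_helix_ca(length(res_a))
  helB0 <- ideal_helix_ca(length(res_b))
  # center each template on its own axis midpoint so rotation acts about the
  # helix center, then offset helix B to keep the chains apart
  helA <- sweep(helA, 2, colMeans(helA))
  helB0 <- sweep(helB0, 2, colMeans(helB0))
  offset <- c(12, 0, 0)
  angles <- with_seed(seed, {
    w <- vapply(spec$components, function(x) x[["weight"]], numeric(1))
    comp <- sample.int(length(w), spec$n_models, replace = TRUE, prob = w)
    vapply(seq_len(spec$n_models), function(i) {
      ci <- spec$components[[comp[i]]]
      stats::rnorm(1, ci[["mean"]], ci[["sd"]])
    }, numeric(1))
  })
  angles <- pmin(pmax(angles, 0), 180)
  n_at <- length(res_a) + length(res_b)
  xyz <- matrix(NA_real_, spec$n_models, 3 * n_at)
  for (i in seq_len(spec$n_models)) {
    R <- rotation_about_y(angles[i])
    helB <- sweep(helB0 %*% t(R), 2, offset, `+`)
    coords <- rbind(helA, helB)
    xyz[i, ] <- as.vector(t(coords))
  }
  atoms <- data.frame(
    eleno = seq_len(n_at), elety = "CA", resid = "ALA",
    chain = "A", resno = c(res_a, res_b)
  )
  structure_ensemble(atoms, xyz, truth = list(angles = angles, spec = spec))
}
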