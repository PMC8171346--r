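test_that("helix axis is exact on ideal helices and respects orientation", {
  h <- tnckit:::ideal_helix_ca(12)
  ax <- helix_axis(h)$axis
  expect_equal(ax, c(0, 0, 1), tolerance = 1e-6)
  # reversed residue order flips the oriented axis
  expect_equal(helix_axis(h[12:1, ])$axis, c(0, 0, -1), tolerance = 1e-6)
  # a known rotation maps the axis accordingly
  R <- tnckit:::rotation_about_y(37)
  expect_equal(helix_axis(h %*% t(R))$axis, as.vector(R %*% c(0, 0, 1)),
               tolerance = 1e-6)
  expect_error(helix_axis(h[1:3, ]), ">= 4")
  expect_error(helix_axis(cbind(1:6, 0, 0)), "collinear")
})

test_that("ab_angle matches constructed geometry and is rigid-motion invariant", {
  ens <- gen_two_helix_ensemble(angle_dist_spec(list(c(110, 0, 1)), n_models = 1),
                                seed = 1)
  expect_equal(ab_angle(ens), 110, tolerance = 0.5)
  # global rotation + translation leaves the angle unchanged
  R <- tnckit:::rotation_about_y(63.7)
  coords <- model_coords(ens, 1) %*% t(R)
  coords <- sweep(coords, 2, c(11, -4, 3), `+`)
  moved <- structure_ensemble(ens$atoms, as.vector(t(coords)))
  expect_equal(ab_angle(moved), ab_angle(ens), tolerance = 1e-6)
})

test_that("open fraction uses a strict threshold and tracks mixture weights", {
  expect_equal(open_fraction(rep(100, 5), n_boot = 10)$fraction, 1)
  expect_equal(open_fraction(rep(110, 5), n_boot = 10)$fraction, 0)  # strict <
  spec <- angle_dist_spec(list(c(110, 5, 0.5), c(150, 5, 0.5)), n_models = 1500)
  ang <- ab_angle(gen_two_helix_ensemble(spec, seed = 3))
  of <- open_fraction(ang, seed = 1)
  # half of the 110-degree component sits below the strict 110 cut
  expect_equal(of$fraction, 0.25, tolerance = 0.05)
  expect_true(of$ci[1] <= of$fraction && of$fraction <= of$ci[2])
  # per-replicate fractions
  rep_id <- rep(1:3, length.out = length(ang))
  pr <- open_fraction(ang, replicate = rep_id, seed = 1)$per_replicate
  expect_length(pr, 3)
  # convergence of the fraction toward the weight below threshold
  big <- ab_angle(gen_two_helix_ensemble(
    angle_dist_spec(list(c(100, 3, 0.6), c(150, 3, 0.4)), n_models = 4000), seed = 5))
  # binomial sampling bound: 3 * sqrt(p (1-p) / n) ~ 0.023 at n = 4000
  expect_lt(abs(open_fraction(big, n_boot = 10)$fraction - 0.6), 0.025)
})

test_that("RMSF is zero for identical or rigidly rotated models and matches the two-point closed form", {
  base <- gen_two_helix_ensemble(angle_dist_spec(list(c(120, 0, 1)), n_models = 1),
                                 seed = 1)
  # rigid-body rotated copies: superposition must null the fluctuation
  R <- tnckit:::rotation_about_y(25)
  rot <- as.vector(t(model_coords(base, 1) %*% t(R)))
  ens <- structure_ensemble(base$atoms, rbind(base$xyz[1, ], rot, base$xyz[1, ]))
  r0 <- rmsf(ens, align_resno = c(14:25, 38:47))
  expect_lt(max(r0$rmsf), 1e-9)
  # jitter one atom (outside the alignment selection) by d in 1 of N models
  N <- 5; d <- 0.6
  ens5 <- gen_two_helix_ensemble(angle_dist_spec(list(c(120, 0, 1)), n_models = N),
                                 seed = 1)
  i <- which(ens5$atoms$resno == 47)
  ens5$xyz[3, 3 * i - 2] <- ens5$xyz[3, 3 * i - 2] + d
  r <- rmsf(ens5, align_resno = 14:25)
  expect_equal(r$rmsf[r$resno == 47], d * sqrt(N - 1) / N, tolerance = 1e-9)
  expect_error(rmsf(ens5, align_resno = 200:210), "empty")
})

test_that("contact maps equal the brute-force oracle in both modes", {
  for (seed in 1:3) {
    ens <- toy_structure(n_res = 50, seed = seed)
    got <- contact_map(ens, "calpha-5")
    want <- brute_force_contacts(ens, "calpha", cutoff = 5, min_sep = 3)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$dist, want$dist, tolerance = 1e-12)
    ensh <- toy_structure_heavy(n_res = 30, seed = seed)
    goth <- contact_map(ensh, "heavy-7")
    wanth <- brute_force_contacts(ensh, "heavy", cutoff = 7, min_sep = 6)
    expect_equal(goth$i, wanth$i)
    expect_equal(goth$j, wanth$j)
    expect_equal(goth$dist, wanth$dist, tolerance = 1e-12)
  }
})

test_that("contact cutoffs and separation rules behave at the boundaries", {
  # two Calpha at 4.9 A with |i-j| = 7: contact in calpha-5 mode
  mk <- function(gap) {
    n <- gap + 1
    coords <- cbind(seq(0, 100, length.out = n), 0, 0)
    coords[n, ] <- coords[1, ] + c(4.9, 0, 0)
    atoms <- data.frame(eleno = 1:n, elety = "CA", resid = "ALA",
                        chain = "A", resno = 1:n)
    structure_ensemble(atoms, as.vector(t(coords)))
  }
  expect_equal(nrow(contact_map(mk(7), "calpha-5")), 1)
  # same pair with |i-j| = 5 in heavy mode: excluded by the >= 6 separation rule
  expect_equal(nrow(contact_map(mk(5), "heavy-7")), 0)
})

test_that("contact-map differences report gained, lost and persistent pairs", {
  ens <- toy_structure(n_res = 40, seed = 4)
  m <- contact_map(ens, "calpha-5")
  same <- diff_contact_map(m, m)
  expect_equal(nrow(same$gained), 0)
  expect_equal(nrow(same$lost), 0)
  expect_equal(nrow(same$persistent), nrow(m))
  expect_true(all(same$persistent$d_occupancy == 0))
  # toggle exactly one pair
  m2 <- m[-1, , drop = FALSE]
  attr(m2, "mode") <- attr(m, "mode")
  dd <- diff_contact_map(m, m2)
  expect_equal(nrow(dd$lost), 1)
  expect_equal(dd$lost$i, m$i[1])
  other <- contact_map(toy_structure(n_res = 40, seed = 9), "heavy-7")
  expect_error(diff_contact_map(m, other), "definitions differ")
})

test_that("ensemble PCA has unit variance-fraction sum, centered projections and exact reconstruction", {
  ens <- gen_two_helix_ensemble(angle_dist_spec(list(c(120, 3, 1)), n_models = 30),
                                seed = 2)
  pc <- pca_ensemble(ens, resno = c(14:25, 38:47))
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(max(abs(colMeans(pc$projections))), 0, tolerance = 1e-10)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # reconstruction from all modes reproduces centered coordinates
  Xc <- pc$projections %*% t(pc$rotation)
  ca <- tnckit:::atom_indices(ens, resno = c(14:25, 38:47), elety = "CA")
  aligned <- tnckit:::align_ensemble(ens, ca)[, tnckit:::xyz_indices(ca)]
  expect_equal(Xc, unname(sweep(aligned, 2, colMeans(aligned))), tolerance = 1e-9)
  # models displaced along one fixed pattern: PC1 carries ~all variance
  base <- ens$xyz[1, ]
  set.seed(5); pat <- rnorm(length(base))
  shift <- t(sapply(seq(-1, 1, length.out = 11), function(a) base + a * pat))
  pc1 <- pca_ensemble(structure_ensemble(ens$atoms, shift),
                      resno = c(14:25, 38:47))
  expect_gt(pc1$variance_fraction[1], 0.99)
})

test_that("1D free-energy landscapes Boltzmann-invert two-state populations", {
  proj <- c(rep(-1, 30), rep(1, 70))
  f <- fel_1d(proj, bins = 4)
  expect_true(any(is.na(f$dG_kT)) || all(f$count > 0))  # empty bins masked
  dg <- f$dG_kT[f$count > 0]
  expect_equal(min(dg), 0)                                # most-occupied bin at 0
  expect_equal(max(dg), -log(30 / 70), tolerance = 1e-12) # well-to-well gap
  # uniform occupancy: flat landscape at 0
  u <- fel_1d(rep(1:10 - 0.5, each = 10), bins = 10)
  expect_true(all(abs(u$dG_kT[u$count > 0]) < 1e-12))
  expect_error(fel_1d(proj, bins = 1), "2 bins")
})

test_that("Welch test conventions hold", {
  expect_equal(welch_t(c(1, 1, 1), c(1, 1, 1))$p, 1)
  a <- c(0.1, 0.2, 0.3, 0.25); b <- c(0.5, 0.6, 0.55, 0.65)
  w1 <- welch_t(a, b); w2 <- welch_t(b, a)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  # cross-check against the standard implementation
  tt <- t.test(a, b)
  expect_equal(w1$t, unname(tt$statistic))
  expect_equal(w1$p, tt$p.value)
})
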