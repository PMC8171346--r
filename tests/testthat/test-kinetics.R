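act <- ca_activation(pCa50_act = 5.8, n_act = 1.6)
ref_params <- kinetic_params(kON = 100, kOFF = 150, f = 8, g = 4, activation = act)

random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(kON = 10^runif(1, 1, 3), kOFF = 10^runif(1, 1, 3),
                   f = 10^runif(1, 0, 1.5), g = 10^runif(1, 0, 1.5),
                   activation = ca_activation(runif(1, 5.4, 6.2), runif(1, 1, 3)))
  })
}

test_that("rate matrix is a generator and activation has its Hill midpoint", {
  for (p in random_params(20)) {
    Q <- rate_matrix(p, runif(1, 4, 7))
    # generator property, relative to the largest rate in the matrix
    expect_lt(max(abs(colSums(Q))) / max(abs(Q)), 1e-14)
  }
  expect_equal(ca_occupancy(act, act$pCa50_act), 0.5)
  # no Ca: B absorbing, attached occupancy drains to ~0
  ss <- steady_state(ref_params, 9)
  expect_lt(ss$M, 1e-4)
})

test_that("analytic steady state matches long-time ODE integration", {
  for (p in random_params(100, seed = 7)) {
    pca <- runif(1, 4.5, 6.5)
    Q <- rate_matrix(p, pca)
    rates <- c(p$kON, p$kOFF, p$f, p$g)
    sol <- deSolve::ode(c(B = 1, C = 0, M = 0),
                        times = c(0, 1000 / min(rates)),
                        func = function(t, y, parms) list(as.vector(Q %*% y)),
                        parms = NULL, rtol = 1e-11, atol = 1e-13)
    ss <- steady_state(p, pca)
    expect_equal(unname(unlist(ss[1, c("B", "C", "M")])),
                 unname(sol[2, c("B", "C", "M")]), tolerance = 1e-8)
    expect_equal(ss$B + ss$C + ss$M, 1, tolerance = 1e-12)
    expect_true(all(ss[1, c("B", "C", "M")] >= 0))
  }
})

test_that("degenerate kinetics are rejected or handled per contract", {
  expect_error(kinetic_params(0, 1, 1, 1), "positive")
  expect_error(kinetic_params(1, -2, 1, 1), "positive")
  expect_error(kinetic_params(100, 100, 0, 1), "positive")
  # f -> 0+ drains the attached state; normalized force stays well defined
  tiny <- steady_state(kinetic_params(100, 100, 1e-12, 1, act), c(5.5, 4.0))
  expect_lt(max(tiny$M), 1e-11)
  expect_equal(tiny$force[2], 1)
  # kOFF -> 0 limit: B empties, M/C -> f/g (use a tiny but positive kOFF)
  p <- kinetic_params(100, 1e-9, 8, 4, act)
  ss <- steady_state(p, 5.0)
  expect_lt(ss$B, 1e-9)
  expect_equal(ss$M / ss$C, 2, tolerance = 1e-6)
})

test_that("kTR approaches f + g at saturating Ca with fast, mostly-on regulation", {
  p <- kinetic_params(kON = 5e4, kOFF = 500, f = 5, g = 5, activation = act)
  expect_equal(ktr(p, 4.0), 10, tolerance = 0.02)
  expect_equal(ktr(p, 4.0, method = "simulate"), 10, tolerance = 0.02)
})

test_that("eigen and simulated kTR agree when relaxation modes are separated", {
  set.seed(11)
  n_checked <- 0
  for (p in random_params(50, seed = 11)) {
    pca <- runif(1, 4.5, 6.0)
    Q <- rate_matrix(p, pca)
    ev <- sort(abs(Re(eigen(Q, only.values = TRUE)$values)))
    ev <- ev[ev > 1e-9]
    if (length(ev) < 2 || ev[2] / ev[1] < 3) next  # modes not separated
    k_sim <- tryCatch(ktr(p, pca, method = "simulate"), error = function(e) NA)
    if (is.na(k_sim)) next
    n_checked <- n_checked + 1
    expect_equal(ktr(p, pca, method = "eigen"), k_sim, tolerance = 0.05)
  }
  expect_gt(n_checked, 20)
})

test_that("probability is conserved along the kTR simulation", {
  Q <- rate_matrix(ref_params, 5.6)
  ss <- steady_state(ref_params, 5.6)
  bc <- ss$B + ss$C
  sol <- deSolve::ode(c(B = ss$B / bc, C = ss$C / bc, M = 0),
                      times = seq(0, 2, length.out = 300),
                      func = function(t, y, parms) list(as.vector(Q %*% y)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(rowSums(sol[, c("B", "C", "M")]) - 1)), 1e-9)
})

test_that("Hill fits recover noiseless generator truth exactly", {
  for (pc50 in c(5.2, 5.56, 5.72)) {
    spec <- genotype_mech_spec("WT", pCa50 = pc50, nHill = 2, noise_sd = 0,
                               replicates = 1)
    d <- gen_force_pca(spec, seed = 1)
    for (np in c(2, 3, 4)) {
      fit <- fit_hill(d, n_params = np)
      expect_equal(fit$pCa50, pc50, tolerance = 1e-6)
      expect_equal(fit$nHill, 2, tolerance = 1e-6)
    }
    f4 <- fit_hill(d, n_params = 4)
    expect_equal(f4$Fmin, 0, tolerance = 1e-6)
    expect_equal(f4$Fmax, 1, tolerance = 1e-6)
  }
  expect_error(fit_hill(data.frame(pCa = c(6, 5, 4), force = c(0, .5, 1)),
                        n_params = 4), "distinct pCa")
})

test_that("three-state joint fit inverts the noiseless generator to <= 0.1%", {
  d <- gen_mechanics_3state(ref_params, noise = 0, seed = 1, replicates = 1)
  fit <- fit_three_state(d, kON_fixed = 100, activation = act)
  expect_true(fit$converged)
  expect_equal(fit$f, 8, tolerance = 1e-3)
  expect_equal(fit$g, 4, tolerance = 1e-3)
  expect_equal(fit$kOFF, 150, tolerance = 1e-3)
})

test_that("three-state fit recovers rates from noisy replicated data", {
  errs <- sapply(1:12, function(s) {
    d <- gen_mechanics_3state(ref_params, noise = 0.03, seed = s, replicates = 6)
    fit <- fit_three_state(d, kON_fixed = 100, activation = act, n_starts = 4)
    abs(c(fit$f, fit$g, fit$kOFF) / c(8, 4, 150) - 1)
  })
  expect_lt(median(errs), 0.15)
})

test_that("perturbation envelopes scale jointly and bracket the fitted locus", {
  env <- perturbation_envelope(ref_params, fractions = c(-0.03, 0, 0.03),
                               pCa_grid = seq(6.5, 4, by = -0.25))
  base <- env[env$fraction == 0, ]
  up <- env[env$fraction == 0.03, ]
  dn <- env[env$fraction == -0.03, ]
  # joint rate scaling leaves steady-state force untouched and scales kTR
  expect_equal(up$force, base$force, tolerance = 1e-12)
  expect_equal(up$ktr, base$ktr * 1.03, tolerance = 1e-10)
  expect_equal(dn$ktr, base$ktr * 0.97, tolerance = 1e-10)
  # +3% lies above -3% pointwise in kTR at matched force
  expect_true(all(up$ktr > dn$ktr))
})
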