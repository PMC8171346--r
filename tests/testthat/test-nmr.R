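test_that("CSP follows the weighted 1H/15N combination exactly", {
  ref <- data.frame(residue = 1:4, dH_ppm = 8, dN_ppm = 115)
  qry <- ref
  qry$dH_ppm <- ref$dH_ppm + c(0, 0.03, 0.05, -0.02)
  qry$dN_ppm <- ref$dN_ppm + c(0, 0.10, 0.00, 0.20)
  prof <- csp(ref, qry)
  expect_equal(prof$csp[1], 0)
  expect_equal(prof$csp[2], sqrt(0.03^2 + 0.1 * 0.10^2))  # ~0.0436 ppm
  expect_equal(prof$csp[3], 0.05)                          # single-axis case
  # symmetric in magnitude under swap
  expect_equal(csp(qry, ref)$csp, prof$csp)
  # unshared residues reported, not imputed
  prof2 <- csp(ref, qry[-1, ])
  expect_equal(attr(prof2, "missing"), 1)
  expect_error(csp(ref, data.frame(residue = 9, dH_ppm = 8, dN_ppm = 115)),
               "shared")
})

test_that("mean + k SD flags use the population SD and nest", {
  vals <- c(rep(0, 100), 5)
  f1 <- flag_above(vals, 1)
  f2 <- flag_above(vals, 2)
  expect_true(f1[101] && f2[101])
  expect_equal(sum(f1), 1)
  expect_true(all(which(f2) %in% which(f1)))  # nested flag sets
  expect_equal(sum(flag_above(rep(1, 10), 1)), 0)
  # k = 0 flags everything strictly above the mean
  expect_equal(sum(flag_above(c(1, 2, 3), 0)), 1)
})

test_that("temperature coefficients recover exact linear slopes", {
  temps <- c(15, 25, 35, 45)
  pls <- lapply(temps, function(Tc) {
    data.frame(residue = 1:3,
               dH_ppm = c(8 - 4.5e-3 * Tc,     # -4.5 ppb/C
                          8 + 2.0e-3 * Tc,     # +2.0 ppb/C
                          8),                  # flat
               dN_ppm = 115, condition = Tc)
  })
  tc <- temp_coeff(pls)
  expect_equal(tc$slope_ppb_per_C, c(-4.5, 2.0, 0), tolerance = 1e-9)
  expect_equal(tc$r2[1:2], c(1, 1), tolerance = 1e-12)
  expect_true(tc$flat[3])
  expect_equal(tc$r2[3], 0)
})

test_that("relaxation-rate fits invert the generator", {
  dec <- gen_relaxation_decays(c(`5` = 1.5, `6` = 0.8, `7` = 0),
                               noise = 0, seed = 1)
  fr <- fit_rate(dec)
  expect_equal(fr$rate, c(1.5, 0.8, 0), tolerance = 1e-6)
  expect_true(all(fr$converged))
  # 2% noise, many residues: median relative error stays small
  rates <- setNames(runif(100, 0.5, 3), 1:100)
  frn <- fit_rate(gen_relaxation_decays(rates, noise = 0.02, seed = 3))
  rel <- abs(frn$rate[order(as.integer(frn$residue))] / unname(rates) - 1)
  expect_lt(median(rel), 0.05)
})

test_that("R2/R1 profiling splits domains and flags elevated ratios", {
  r1 <- setNames(rep(1, 40), 1:40)
  r2 <- setNames(c(rep(10, 19), 20, rep(5, 20)), 1:40)  # residue 20 elevated
  out <- r2_over_r1(r1, r2, domain_split = list(N = 1:20, C = 21:161))
  expect_equal(out$profile$ratio[out$profile$residue == 20], 20)
  expect_true(out$profile$flag[out$profile$residue == 20])
  expect_equal(sum(out$profile$flag), 1)
  expect_equal(out$domains$mean[out$domains$domain == "C"], 5)
  # constructed domain offset is recovered in the domain means
  expect_equal(diff(out$domains$mean), -5.5, tolerance = 1e-12)
  # R2 = R1 everywhere: all ratios 1, nothing flagged
  flat <- r2_over_r1(r1, r1, domain_split = list(N = 1:20, C = 21:161))
  expect_true(all(flat$profile$ratio == 1))
  expect_false(any(flat$profile$flag))
  # R1 = 0 masked
  r1z <- r1; r1z["3"] <- 0
  masked <- r2_over_r1(r1z, r2, domain_split = list(N = 1:20, C = 21:161))
  expect_true(is.na(masked$profile$ratio[masked$profile$residue == 3]))
})

test_that("R2eff matches its closed form and sign convention", {
  expect_equal(r2eff(100, 100, 0.04), 0)
  expect_equal(r2eff(100, 50, 0.04), log(2) / 0.04)   # 17.33 1/s
  expect_equal(r2eff(100, 50, 0.02), 2 * r2eff(100, 50, 0.04))
  x <- 0.37
  expect_equal(r2eff(1, exp(-x), 0.05), x / 0.05, tolerance = 1e-12)
  expect_equal(r2eff(100, 50, 0.04, as_printed = TRUE), -log(2) / 0.04)
  expect_error(r2eff(0, 50, 0.04), "positive")
})

test_that("exchange-regime classification follows the two-frequency rules", {
  # cohort of 20 quiet residues, one dispersing, one elevated-flat
  g <- gen_cpmg(R20 = rep(8, 22), Rex = c(rep(0, 20), 10, 0),
                kex = 1500, seed = 1)
  r50 <- with(g[g$nu_hz == 50, ], setNames(r2eff(I0, intensity, T_s), residue))
  r1000 <- with(g[g$nu_hz == 1000, ], setNames(r2eff(I0, intensity, T_s), residue))
  r50["22"] <- r1000["22"] <- mean(r50[1:20]) + 8   # flat but hot
  cls <- classify_exchange(r50, r1000)
  expect_equal(cls$class[cls$residue == "21"], "intermediate")
  expect_equal(cls$class[cls$residue == "22"], "fast")
  expect_true(all(cls$class[cls$residue %in% as.character(1:20)] == "none"))
  # invariant to intensity rescaling (rates only)
  expect_identical(classify_exchange(r50 * 1, r1000 * 1)$class, cls$class)
  expect_error(classify_exchange(r50[1:3], r1000[1:3]), ">= 5")
})

test_that("shared-Kd titration fits invert the generator across a Kd sweep", {
  cspmax <- c(`10` = 0.25, `30` = 0.12, `70` = 0.18)
  for (kd in c(1, 10, 20, 100, 1000)) {   # 0.01x to 10x Pt
    pls <- gen_titration_peaklists(Kd = kd, CSPmax = cspmax, Pt = 100,
                                   noise = 0, seed = 1)
    fit <- suppressWarnings(fit_kd(titration_csp(pls), Pt = 100))
    expect_equal(fit$Kd, kd, tolerance = 0.01)
    expect_equal(unname(fit$CSPmax), unname(cspmax), tolerance = 0.01)
  }
  # tight-binding limit: stoichiometric break at L = Pt
  pls0 <- gen_titration_peaklists(Kd = 1e-6, CSPmax = c(`1` = 0.2), Pt = 100,
                                  ligand_concs = c(0, 25, 50, 75, 100, 150),
                                  noise = 0, seed = 1)
  tc <- titration_csp(pls0)
  expect_equal(tc$csp[tc$ligand == 100], 0.2, tolerance = 1e-3)
  expect_equal(tc$csp[tc$ligand == 50], 0.1, tolerance = 1e-3)
  # first point already saturating: Kd ill-conditioned, warn
  sat <- gen_titration_peaklists(Kd = 0.5, CSPmax = c(`1` = 0.2), Pt = 20,
                                 ligand_concs = c(0, 150, 160, 170, 180),
                                 noise = 0, seed = 1)
  expect_warning(fit_kd(titration_csp(sat), Pt = 20), "saturation")
})
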