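#' Chemical shift perturbation between two peak lists
#'
#' CSP per shared residue from the weighted 1H/15N shift distance
#' CSP = sqrt((dH)^2 + 0.1 * (dN)^2) in ppm. Residues present in only one
#' list are reported, never imputed.
#'
#' @param reference,query PeakList data.frames with columns `residue`,
#'   `dH_ppm`, `dN_ppm`.
#' @return A `CSPProfile` data.frame (residue, d_dH, d_dN, csp) with
#'   attribute `missing` listing unshared residues; nested outlier flags
#'   are added by [flag_above()].
#' @export
csp <- function(reference, query) {
  shared <- intersect(reference$residue, query$residue)
  if (!length(shared)) stop_("no residues shared between the two peak lists")
  r <- reference[match(shared, reference$residue), ]
  q <- query[match(shared, query$residue), ]
  d_dH <- q$dH_ppm - r$dH_ppm
  d_dN <- q$dN_ppm - r$dN_ppm
  out <- data.frame(residue = shared, d_dH = d_dH, d_dN = d_dN,
                    csp = sqrt(d_dH^2 + 0.1 * d_dN^2))
  attr(out, "missing") <- sort(c(setdiff(reference$residue, shared),
                                 setdiff(query$residue, shared)))
  structure(out, class = c("CSPProfile", "data.frame"))
}

#' Flag values above mean + k SD
#'
#' Population (divide-by-n) standard deviation over the stated residue
#' subset; a value is flagged when strictly greater than mean + k * SD.
#'
#' @param values named or unnamed numeric vector (e.g. CSP per residue).
#' @param k SD multiple (e.g. 1 or 2).
#' @param subset optional index/logical subset over which mean and SD are
#'   computed (flags are still evaluated for all values).
#' @return logical vector of flags.
#' @export
flag_above <- function(values, k = 1, subset = NULL) {
  if (length(values) < 3) stop_("need >= 3 values to define mean + k SD")
  base <- if (is.null(subset)) values else values[subset]
  m <- mean(base)
  s <- sqrt(mean((base - m)^2))
  values > m + k * s
}

#' Amide-proton temperature coefficients
#'
#' Ordinary least-squares slope of the 1H shift (converted to ppb) against
#' temperature (degC) per residue. Residues with fewer than 3 temperatures
#' are skipped with a warning; a constant shift yields slope 0 with R^2
#' reported as 0 and flagged.
#'
#' @param peaklists list of PeakList data.frames whose `condition` holds the
#'   temperature in degC.
#' @return data.frame (residue, slope_ppb_per_C, intercept_ppb, r2, flat).
#' @export
temp_coeff <- function(peaklists) {
  all <- do.call(rbind, peaklists)
  out <- lapply(split(all, all$residue), function(d) {
    if (nrow(d) < 3) {
      warn_("residue %s skipped: fewer than 3 temperatures", d$residue[1])
      return(NULL)
    }
    y <- d$dH_ppm * 1000  # ppm -> ppb
    x <- as.numeric(d$condition)
    if (stats::sd(y) == 0) {
      return(data.frame(residue = d$residue[1], slope_ppb_per_C = 0,
                        intercept_ppb = y[1], r2 = 0, flat = TRUE))
    }
    fit <- stats::lm(y ~ x)
    # summary() warns on numerically perfect lines; the R^2 is still valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(residue = d$residue[1],
               slope_ppb_per_C = stats::coef(fit)[[2]],
               intercept_ppb = stats::coef(fit)[[1]],
               r2 = r2, flat = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$residue), ]
}

#' Fit mono-exponential relaxation decays
#'
#' Nonlinear fit of I(t) = I0 * exp(-R * t) per residue with the initial
#' guess taken from a log-linear regression.
#'
#' @param decays data.frame (residue, delay_s, intensity), e.g. from
#'   [gen_relaxation_decays()].
#' @return data.frame (residue, rate, rate_se, converged).
#' @export
fit_rate <- function(decays) {
  out <- lapply(split(decays, decays$residue), function(d) {
    if (nrow(d) < 4 || any(d$intensity <= 0)) {
      return(data.frame(residue = d$residue[1], rate = NA_real_,
                        rate_se = NA_real_, converged = FALSE))
    }
    if (stats::sd(log(d$intensity)) < 1e-12) {
      # flat decay: rate is zero to machine precision
      return(data.frame(residue = d$residue[1], rate = 0, rate_se = 0,
                        converged = TRUE))
    }
    lf <- stats::lm(log(d$intensity) ~ d$delay_s)
    r0 <- -stats::coef(lf)[[2]]
    fit <- try(minpack.lm::nlsLM(intensity ~ I0 * exp(-R * delay_s), data = d,
                                 start = list(I0 = exp(stats::coef(lf)[[1]]),
                                              R = max(r0, 0)),
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(data.frame(residue = d$residue[1], rate = NA_real_,
                        rate_se = NA_real_, converged = FALSE))
    }
    sm <- summary(fit)$coefficients
    data.frame(residue = d$residue[1], rate = sm["R", "Estimate"],
               rate_se = sm["R", "Std. Error"], converged = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' R2/R1 ratio profile with per-domain statistics
#'
#' Ratios per residue plus per-domain mean and SD (population SD) and flags
#' for residues more than 1 SD above their domain mean; residues with
#' R1 = 0 are masked. The default split places the N-domain before the
#' D/E-linker boundary at residue 90.
#'
#' @param r1,r2 named numeric vectors of rates (names = residue numbers).
#' @param domain_split named list of residue ranges
#'   (default `list(N = 1:89, C = 90:161)`).
#' @param k SD multiple for flagging (default 1).
#' @return list: `profile` data.frame (residue, ratio, domain, flag) and
#'   `domains` data.frame (domain, mean, sd).
#' @export
r2_over_r1 <- function(r1, r2, domain_split = list(N = 1:89, C = 90:161),
                       k = 1) {
  shared <- intersect(names(r1), names(r2))
  if (!length(shared)) stop_("no residues shared between R1 and R2")
  ratio <- ifelse(r1[shared] == 0, NA_real_, r2[shared] / r1[shared])
  resno <- as.integer(shared)
  domain <- rep(NA_character_, length(resno))
  for (d in names(domain_split)) domain[resno %in% domain_split[[d]]] <- d
  prof <- data.frame(residue = resno, ratio = unname(ratio), domain = domain)
  doms <- do.call(rbind, lapply(names(domain_split), function(d) {
    v <- prof$ratio[prof$domain == d & !is.na(prof$ratio)]
    data.frame(domain = d, mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)))
  }))
  prof$flag <- FALSE
  for (d in names(domain_split)) {
    sel <- which(prof$domain == d & !is.na(prof$ratio))
    thr <- doms$mean[doms$domain == d] + k * doms$sd[doms$domain == d]
    prof$flag[sel] <- prof$ratio[sel] > thr
  }
  list(profile = prof[order(prof$residue), ], domains = doms)
}

#' Effective transverse relaxation rate from CPMG intensities
#'
#' Computed as (1/T) * ln(I0 / I_CPMG), which is positive for attenuated
#' signal. `as_printed = TRUE` flips the sign to reproduce the literal
#' formula -1/T * ln(I0/I_CPMG) for compatibility.
#'
#' @param I0 reference intensity (no CPMG block), > 0.
#' @param Icpmg intensity with the CPMG block, > 0.
#' @param T_relax relaxation period in s, > 0.
#' @param as_printed flip to the literal sign convention.
#' @return R2eff in 1/s (vectorized).
#' @export
r2eff <- function(I0, Icpmg, T_relax, as_printed = FALSE) {
  if (any(I0 <= 0) || any(Icpmg <= 0)) stop_("intensities must be positive")
  if (any(T_relax <= 0)) stop_("relaxation period must be positive")
  out <- log(I0 / Icpmg) / T_relax
  if (as_printed) -out else out
}

#' Classify exchange regime from two-point CPMG dispersion
#'
#' Implements the qualitative two-frequency criterion: a residue is in
#' `"fast"` exchange when its 50 and 1000 Hz R2eff values are nearly
#' identical (|delta| <= eps) yet elevated more than 1 SD above the cohort
#' average, `"intermediate"` when the dispersion decays (R2eff(50) -
#' R2eff(1000) > delta) and R2eff(50) is similarly elevated, else
#' `"none"`.
#'
#' @param r2eff_50,r2eff_1000 named vectors of R2eff (1/s) per residue.
#' @param eps flat-dispersion tolerance; default `max(2, 0.1 * cohort mean)`.
#' @param delta minimum dispersion decay for `"intermediate"`; default `eps`.
#' @return data.frame (residue, r2eff_50, r2eff_1000, delta, class).
#' @export
classify_exchange <- function(r2eff_50, r2eff_1000, eps = NULL, delta = NULL) {
  shared <- intersect(names(r2eff_50), names(r2eff_1000))
  if (length(shared) < 5) stop_("cohort must contain >= 5 residues")
  a <- r2eff_50[shared]; b <- r2eff_1000[shared]
  mid <- (a + b) / 2
  cohort_mean <- mean(mid)
  cohort_sd <- sqrt(mean((mid - cohort_mean)^2))
  eps <- eps %||% max(2, 0.1 * cohort_mean)
  delta <- delta %||% eps
  gate <- cohort_mean + cohort_sd
  d <- a - b
  cls <- ifelse(abs(d) <= eps & mid > gate, "fast",
                ifelse(d > delta & a > gate, "intermediate", "none"))
  data.frame(residue = shared, r2eff_50 = unname(a), r2eff_1000 = unname(b),
             delta = unname(d), class = unname(cls))
}

#' Fit a shared Kd to CSP titration data
#'
#' Global least-squares fit of CSP(L) = CSPmax * fb(L; Pt, Kd) where fb is
#' the 1:1 quadratic bound-fraction isotherm; one Kd is shared across
#' residues with a per-residue CSPmax (profiled linearly), matching a
#' single-affinity titration. Warns when saturation is not approached.
#'
#' @param data data.frame (ligand, csp) or (residue, ligand, csp); ligand
#'   in uM, csp in ppm; >= 4 ligand points including 0.
#' @param Pt total protein concentration (uM).
#' @return A `TitrationFit`: `Kd` (uM) with `Kd_se`, per-residue `CSPmax`,
#'   `Pt`, `rss`.
#' @export
fit_kd <- function(data, Pt) {
  stopifnot(all(c("ligand", "csp") %in% names(data)), Pt > 0)
  if (!"residue" %in% names(data)) data$residue <- 1L
  if (length(unique(data$ligand)) < 4 || !any(data$ligand == 0)) {
    stop_("need >= 4 ligand concentrations including 0")
  }
  nz <- data[data$ligand > 0, ]
  first_csp <- mean(nz$csp[nz$ligand == min(nz$ligand)])
  if (max(nz$csp) < 2 * first_csp) {
    warn_("saturation not approached (max CSP < 2x first-point CSP); Kd may be ill-conditioned")
  }
  rss_of <- function(logKd) {
    Kd <- exp(logKd)
    fb <- bound_fraction(data$ligand, Pt, Kd)
    sum(unlist(lapply(split(seq_len(nrow(data)), data$residue), function(ix) {
      f <- fb[ix]; y <- data$csp[ix]
      amp <- if (sum(f^2) > 0) sum(f * y) / sum(f^2) else 0
      (y - amp * f)^2
    })))
  }
  opt <- stats::optimize(rss_of, interval = log(c(1e-3, 1e5)), tol = 1e-10)
  Kd <- exp(opt$minimum)
  fb <- bound_fraction(data$ligand, Pt, Kd)
  CSPmax <- vapply(split(seq_len(nrow(data)), data$residue), function(ix) {
    sum(fb[ix] * data$csp[ix]) / sum(fb[ix]^2)
  }, numeric(1))
  # curvature-based SE on log Kd, delta method to Kd scale
  h <- 1e-4
  curv <- (rss_of(opt$minimum + h) - 2 * opt$objective + rss_of(opt$minimum - h)) / h^2
  dof <- max(nrow(data) - length(CSPmax) - 1, 1)
  Kd_se <- if (curv > 0) Kd * sqrt(2 * opt$objective / dof / curv) else NA_real_
  structure(list(Kd = Kd, Kd_se = Kd_se, CSPmax = CSPmax, Pt = Pt,
                 rss = opt$objective),
            class = "TitrationFit")
}

#' Extract per-residue CSP-vs-ligand data from a titration peak-list series
#'
#' Convenience bridge from [gen_titration_peaklists()] output (or any list
#' of peak lists whose `condition` is the ligand concentration) to the
#' input of [fit_kd()]: the zero-ligand list is the CSP reference.
#'
#' @param peaklists named list of PeakList data.frames.
#' @return data.frame (residue, ligand, csp).
#' @export
titration_csp <- function(peaklists) {
  concs <- as.numeric(names(peaklists))
  ref <- peaklists[[which(concs == 0)[1]]]
  out <- lapply(seq_along(peaklists), function(k) {
    p <- csp(ref, peaklists[[k]])
    data.frame(residue = p$residue, ligand = concs[k], csp = p$csp)
  })
  do.call(rbind, out)
}
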