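#' Three-state sarcomere kinetic model
#'
#' Linear scheme B <-> C <-> M over the states of a thin-filament regulatory
#' unit and its cross-bridges: B (blocked), C (permissive but detached) and M
#' (attached, force-generating). Ca2+ enters only the B -> C transition
#' through a Hill occupancy of regulatory site II:
#'
#'   B -> C : kON * alpha(pCa),   C -> B : kOFF
#'   C -> M : f,                  M -> C : g
#'
#' with alpha(pCa) = 1 / (1 + 10^(n_act * (pCa - pCa50_act))). Force is
#' proportional to the occupancy of M. All rates are in 1/s.
#'
#' @param kON regulatory-unit on-rate scale (1/s).
#' @param kOFF regulatory-unit off-rate (1/s).
#' @param f cross-bridge attachment rate (1/s).
#' @param g cross-bridge detachment rate (1/s).
#' @param activation a [ca_activation()] linkage.
#' @return A `KineticParams` list.
#' @export
kinetic_params <- function(kON, kOFF, f, g, activation = ca_activation()) {
  rates <- c(kON = kON, kOFF = kOFF, f = f, g = g)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop_("all rates must be positive and finite; got %s",
          paste(sprintf("%s=%g", names(rates), rates), collapse = ", "))
  }
  structure(list(kON = kON, kOFF = kOFF, f = f, g = g,
                 activation = activation),
            class = "KineticParams")
}

#' Ca2+-activation linkage for the three-state model
#'
#' Hill occupancy of the regulatory Ca2+ site as a function of pCa.
#'
#' @param pCa50_act pCa of half-maximal site occupancy.
#' @param n_act Hill coefficient of occupancy (> 0).
#' @return A `CaActivation` list.
#' @export
ca_activation <- function(pCa50_act = 5.8, n_act = 1.6) {
  if (!is.finite(n_act) || n_act <= 0) stop_("n_act must be > 0")
  structure(list(pCa50_act = pCa50_act, n_act = n_act),
            class = "CaActivation")
}

#' Regulatory-site Ca2+ occupancy
#' @param activation a [ca_activation()].
#' @param pCa vector of pCa values.
#' @return occupancy in (0, 1).
#' @export
ca_occupancy <- function(activation, pCa) {
  1 / (1 + 10^(activation$n_act * (pCa - activation$pCa50_act)))
}

#' Generator (rate) matrix of the three-state scheme
#'
#' Returns the 3x3 generator Q over states (B, C, M) such that
#' dP/dt = Q %*% P; every column sums to zero (probability conservation).
#'
#' @param params a [kinetic_params()].
#' @param pCa pCa at which to evaluate the Ca2+-dependent B -> C rate.
#' @return 3x3 matrix with dimnames B, C, M.
#' @export
rate_matrix <- function(params, pCa) {
  stopifnot(inherits(params, "KineticParams"))
  a <- ca_occupancy(params$activation, pCa)
  kBC <- params$kON * a
  Q <- matrix(c(
    -kBC,          params$kOFF,                 0,
     kBC, -(params$kOFF + params$f),     params$g,
       0,              params$f,        -params$g
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("B", "C", "M"), c("B", "C", "M")))
  Q
}

#' Steady-state occupancies and normalized force
#'
#' Solves the null space of the generator analytically via detailed balance
#' of the linear chain. Force is defined as M(pCa) normalized to M at
#' saturating Ca2+ (pCa 4.0).
#'
#' @param params a [kinetic_params()].
#' @param pCa vector of pCa values.
#' @return data.frame with columns pCa, B, C, M, force.
#' @export
steady_state <- function(params, pCa) {
  stopifnot(inherits(params, "KineticParams"))
  occ <- function(p) {
    a <- ca_occupancy(params$activation, p)
    if (a <= 0) return(c(B = 1, C = 0, M = 0))
    # chain balance: B/C = kOFF/(kON a); M/C = f/g
    b_over_c <- params$kOFF / (params$kON * a)
    m_over_c <- params$f / params$g
    C <- 1 / (1 + b_over_c + m_over_c)
    c(B = b_over_c * C, C = C, M = m_over_c * C)
  }
  res <- t(vapply(pCa, occ, numeric(3)))
  m_ref <- occ(4.0)[["M"]]
  if (m_ref <= 0) stop_("zero attached occupancy at reference pCa 4.0 (f = 0?)")
  data.frame(pCa = pCa, B = res[, "B"], C = res[, "C"], M = res[, "M"],
             force = res[, "M"] / m_ref)
}

#' Rate of isometric tension redevelopment (kTR)
#'
#' Models the release--restretch maneuver as instantaneous cross-bridge
#' detachment with unchanged regulatory state: the system starts from M = 0
#' with B and C renormalized from their steady-state ratio, and M(t) relaxes
#' back to steady state.
#'
#' `method = "eigen"` reports the smallest-magnitude nonzero eigenvalue of
#' the generator (the slow relaxation mode that dominates the force rise).
#' `method = "simulate"` integrates the ODE and fits a mono-exponential to
#' the 5--95% force-rise window; the two agree within a few percent whenever
#' the two relaxation modes are well separated.
#'
#' @param params a [kinetic_params()].
#' @param pCa pCa value (scalar) or vector.
#' @param method `"eigen"` (default) or `"simulate"`.
#' @return kTR in 1/s (vector over `pCa`).
#' @export
ktr <- function(params, pCa, method = c("eigen", "simulate")) {
  method <- match.arg(method)
  vapply(pCa, function(p) {
    Q <- rate_matrix(params, p)
    if (method == "eigen") {
      ev <- eigen(Q, only.values = TRUE)$values
      ev <- Re(ev[abs(Re(ev)) > 1e-12 * max(abs(Re(ev)))])
      if (!length(ev)) stop_("degenerate generator: no nonzero eigenvalue")
      min(abs(ev))
    } else {
      ktr_simulate(params, p, Q)
    }
  }, numeric(1))
}

# Post-slack ODE integration + mono-exponential fit over the 5-95% rise.
ktr_simulate <- function(params, pCa, Q) {
  ss <- steady_state(params, pCa)
  occ <- c(ss$B[1], ss$C[1], ss$M[1])
  bc <- occ[1] + occ[2]
  y0 <- c(B = occ[1] / bc, C = occ[2] / bc, M = 0)
  # integrate long enough to cover the slowest relevant mode
  rates <- c(params$kON, params$kOFF, params$f, params$g)
  t_end <- 10 / min(rates)
  times <- seq(0, t_end, length.out = 400)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(as.vector(Q %*% y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  m <- sol[, "M"]
  m_inf <- occ[3]
  lo <- 0.05 * m_inf
  hi <- 0.95 * m_inf
  win <- which(m >= lo & m <= hi)
  if (length(win) < 5) stop_("kTR fit window too small: slow mode unresolved at pCa %g", pCa)
  tt <- sol[win, "time"]
  dm <- pmax(m_inf - m[win], .Machine$double.eps)
  # log-linear start, then nonlinear refinement
  k0 <- max(-stats::coef(stats::lm(log(dm) ~ tt))[[2]], 1e-6)
  fit <- try(stats::nls(mm ~ m_inf - A * exp(-k * t),
                        data = list(mm = m[win], t = tt, m_inf = m_inf),
                        start = list(A = dm[1] * exp(k0 * tt[1]), k = k0),
                        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop_("kTR mono-exponential fit failed at pCa %g: %s", pCa,
          attr(fit, "condition")$message)
  }
  stats::coef(fit)[["k"]]
}

#' Hill regression of force-pCa (or stiffness-pCa) data
#'
#' Fits F(pCa) = Fmin + (Fmax - Fmin) / (1 + 10^(nHill * (pCa - pCa50))).
#' The 2-parameter form fixes Fmin = 0 and Fmax = 1; the 3-parameter form
#' additionally estimates Fmax; the 4-parameter form frees both plateaus.
#'
#' @param data data.frame with columns `pCa` and the response column.
#' @param response `"force"` (default) or `"ss"` (sinusoidal stiffness).
#' @param n_params 2, 3 or 4.
#' @return A `HillFit` list with estimates, standard errors, residual sum of
#'   squares and the fitted `curve` function.
#' @export
fit_hill <- function(data, response = "force", n_params = 4) {
  stopifnot(response %in% names(data), "pCa" %in% names(data),
            n_params %in% c(2, 3, 4))
  y <- data[[response]]
  x <- data$pCa
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(unique(x)) < n_params + 1) {
    stop_("need at least %d distinct pCa values for a %d-parameter Hill fit",
          n_params + 1, n_params)
  }
  starts <- expand.grid(pCa50 = stats::quantile(x, c(0.35, 0.5, 0.65)),
                        nHill = c(1, 2, 4))
  forms <- list(
    `2` = y ~ 1 / (1 + 10^(nHill * (x - pCa50))),
    `3` = y ~ Fmax / (1 + 10^(nHill * (x - pCa50))),
    `4` = y ~ Fmin + (Fmax - Fmin) / (1 + 10^(nHill * (x - pCa50)))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(pCa50 = unname(starts$pCa50[i]), nHill = starts$nHill[i])
    if (n_params >= 3) st$Fmax <- max(y)
    if (n_params == 4) st$Fmin <- min(y)
    fit <- try(minpack.lm::nlsLM(forms[[as.character(n_params)]],
                                 data = data.frame(x = x, y = y),
                                 start = st,
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop_("Hill fit failed to converge from every start")
  cf <- stats::coef(best$fit)
  se <- summary(best$fit)$coefficients[, "Std. Error"]
  est <- list(pCa50 = cf[["pCa50"]], nHill = cf[["nHill"]],
              Fmin = if (n_params == 4) cf[["Fmin"]] else 0,
              Fmax = if (n_params >= 3) cf[["Fmax"]] else 1)
  if (est$Fmax <= est$Fmin) stop_("degenerate Hill fit: Fmax <= Fmin")
  structure(list(
    pCa50 = est$pCa50, nHill = est$nHill, Fmin = est$Fmin, Fmax = est$Fmax,
    se = se, n_params = n_params, rss = best$rss,
    curve = function(pCa) est$Fmin + (est$Fmax - est$Fmin) /
      (1 + 10^(est$nHill * (pCa - est$pCa50)))
  ), class = "HillFit")
}

#' @export
print.HillFit <- function(x, ...) {
  cat(sprintf("%d-parameter Hill fit: pCa50 = %.3f (SE %.3f), nHill = %.2f, Fmin = %.3f, Fmax = %.3f\n",
              x$n_params, x$pCa50, x$se[["pCa50"]], x$nHill, x$Fmin, x$Fmax))
  invisible(x)
}

# model curves for the joint fit
three_state_curves <- function(f, g, kOFF, kON, activation, pCa) {
  p <- kinetic_params(kON, kOFF, f, g, activation)
  ss <- steady_state(p, pCa)
  list(force = ss$force, ktr = ktr(p, pCa, method = "eigen"))
}

#' Joint (f, g, kOFF) fit of force-pCa and force-kTR data at fixed kON
#'
#' Minimizes the joint weighted residuals of the steady-state force-pCa curve
#' and the kTR-pCa curve over log-parameterized (f, g, kOFF), with kON held
#' fixed. Residuals of each curve are normalized by the data SD of that curve
#' so force and kTR contribute comparably. Multi-start (>= 8 seeded starts)
#' with best-RSS selection guarantees reproducibility.
#'
#' @param data data.frame with columns `pCa`, `force`, `ktr` (paired
#'   observations at >= 4 activation levels).
#' @param kON_fixed regulatory on-rate held fixed during the fit (1/s).
#' @param activation a [ca_activation()] describing Ca2+ sensitivity.
#' @param n_starts number of multi-start initializations (default 8).
#' @param start_seed seed for the start grid (default 1).
#' @return A `ThreeStateFit` list: estimates `f`, `g`, `kOFF` with standard
#'   errors, fixed `kON`, `rss`, and `converged`.
#' @export
fit_three_state <- function(data, kON_fixed, activation,
                            n_starts = 8, start_seed = 1) {
  stopifnot(all(c("pCa", "force", "ktr") %in% names(data)))
  ok <- stats::complete.cases(data[, c("pCa", "force", "ktr")])
  d <- data[ok, ]
  if (length(unique(d$pCa)) < 4) stop_("need paired force/kTR at >= 4 activation levels")
  sd_f <- stats::sd(d$force); sd_k <- stats::sd(d$ktr)
  if (sd_f == 0 || sd_k == 0) stop_("degenerate data: zero variance in force or kTR")
  residfun <- function(theta) {
    f <- exp(theta[1]); g <- exp(theta[2]); kOFF <- exp(theta[3])
    cur <- try(three_state_curves(f, g, kOFF, kON_fixed, activation, d$pCa),
               silent = TRUE)
    if (inherits(cur, "try-error")) return(rep(1e6, 2 * nrow(d)))
    c((cur$force - d$force) / sd_f, (cur$ktr - d$ktr) / sd_k)
  }
  # seeded multi-start in log space around data-driven scales
  k_scale <- max(d$ktr)
  starts <- with_seed(start_seed, {
    base <- log(c(0.6 * k_scale, 0.4 * k_scale, 2 * k_scale))
    t(vapply(seq_len(n_starts), function(i) {
      if (i == 1) base else base + stats::runif(3, -1.5, 1.5)
    }, numeric(3)))
  })
  best <- NULL
  diagnostics <- character()
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(par = starts[i, ], fn = residfun,
                                  control = minpack.lm::nls.lm.control(maxiter = 300)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      diagnostics <- c(diagnostics, sprintf("start %d: %s", i, attr(fit, "condition")$message))
      next
    }
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop_("all three-state fit starts failed:\n%s", paste(diagnostics, collapse = "\n"))
  }
  theta <- best$fit$par
  est <- exp(theta)
  names(est) <- c("f", "g", "kOFF")
  # delta-method SEs from the Jacobian at the optimum (log scale -> rate scale)
  n_res <- 2 * nrow(d)
  dof <- max(n_res - 3, 1)
  sigma2 <- best$rss / dof
  se <- tryCatch({
    J <- num_jacobian(residfun, theta)
    cov_log <- solve(crossprod(J)) * sigma2
    sqrt(diag(cov_log)) * est
  }, error = function(e) rep(NA_real_, 3))
  names(se) <- c("f", "g", "kOFF")
  structure(list(f = est[["f"]], g = est[["g"]], kOFF = est[["kOFF"]],
                 kON = kON_fixed, se = se, rss = best$rss,
                 activation = activation,
                 converged = best$fit$info %in% 1:4),
            class = "ThreeStateFit")
}

#' @export
print.ThreeStateFit <- function(x, ...) {
  cat(sprintf("3-state fit (kON fixed at %g /s): f = %.3g, g = %.3g, kOFF = %.3g /s; RSS = %.4g\n",
              x$kON, x$f, x$g, x$kOFF, x$rss))
  invisible(x)
}

#' Force-kTR perturbation envelopes
#'
#' Recomputes the force-kTR locus after jointly scaling all four rates
#' (kON, kOFF, f, g) by `1 + fraction` for each requested fraction, the
#' uncertainty-envelope construction used to bracket a fitted locus.
#'
#' @param fit a `ThreeStateFit` (or [kinetic_params()]).
#' @param fractions numeric vector, e.g. `c(-0.03, -0.01, 0, 0.01, 0.03)`.
#' @param pCa_grid pCa values at which to trace the locus.
#' @return data.frame with columns fraction, pCa, force, ktr.
#' @export
perturbation_envelope <- function(fit, fractions = c(-0.03, -0.01, 0, 0.01, 0.03),
                                  pCa_grid = seq(7, 4, by = -0.1)) {
  if (inherits(fit, "ThreeStateFit")) {
    if (!isTRUE(fit$converged)) stop_("fit did not converge; no envelope")
    base <- list(kON = fit$kON, kOFF = fit$kOFF, f = fit$f, g = fit$g,
                 activation = fit$activation)
  } else if (inherits(fit, "KineticParams")) {
    base <- fit
  } else stop_("fit must be a ThreeStateFit or KineticParams")
  out <- lapply(fractions, function(fr) {
    s <- 1 + fr
    p <- kinetic_params(base$kON * s, base$kOFF * s, base$f * s, base$g * s,
                        base$activation)
    ss <- steady_state(p, pCa_grid)
    data.frame(fraction = fr, pCa = pCa_grid, force = ss$force,
               ktr = ktr(p, pCa_grid, method = "eigen"))
  })
  do.call(rbind, out)
}
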