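#' Fit the Carreau model to a flow curve
#'
#' Weighted (relative-residual) least squares of
#' `eta(gdot) = eta_inf + (eta0 - eta_inf) * [1 + (tau gdot)^2]^((p-1)/2)`
#' with `eta_inf` fixed at 0 by default (the measured window is far from the
#' infinite-shear limit). Residuals are taken in log viscosity, matching a
#' multiplicative noise model. If no shear thinning is detected (the
#' high-shear viscosity stays within 2 % of the low-shear plateau) a
#' plateau-only fit is returned with `tau` and `p` undefined and
#' `flag = "plateau_only"`.
#'
#' @param curve A [flow_curve()].
#' @param eta_inf Infinite-shear viscosity, Pa s (fixed, default 0).
#' @param n_starts Multi-start count for the optimizer.
#' @return An object of class `carreau_fit`: list with `eta0` (Pa s),
#'   `tau` (s), `p`, `eta_inf`, `chi2_reduced`, `flag` (`NA` or
#'   `"plateau_only"`), `converged`.
#' @export
carreau_fit <- function(curve, eta_inf = 0, n_starts = 6) {
  stopifnot(inherits(curve, "flow_curve"))
  gdot <- curve$shear_rate
  eta <- curve$viscosity
  if (length(gdot) < 8) stop("need at least 8 points spanning the plateau and thinning onset")
  n_lo <- max(3L, ceiling(length(eta) / 8))
  eta_lo <- exp(mean(log(utils::head(eta, n_lo))))
  eta_hi <- exp(mean(log(utils::tail(eta, 3))))
  if (eta_hi > 0.98 * eta_lo) {
    eta0 <- exp(stats::weighted.mean(log(eta), rep(1, length(eta))))
    return(structure(list(eta0 = eta0, tau = NA_real_, p = NA_real_,
                          eta_inf = eta_inf, chi2_reduced = NA_real_,
                          flag = "plateau_only", converged = TRUE),
                     class = "carreau_fit"))
  }
  # theta = (log eta0, log tau, log(1 - p)); p < 1 enforced by transform
  model <- function(th) {
    e0 <- exp(th[1]); tau <- exp(th[2]); p <- 1 - exp(th[3])
    eta_inf + (e0 - eta_inf) * (1 + (tau * gdot)^2)^((p - 1) / 2)
  }
  resid_fn <- function(th) {
    m <- model(th)
    if (any(!is.finite(m)) || any(m <= 0)) return(rep(1e6, length(eta)))
    log(m) - log(eta)
  }
  # tau0 from where eta drops to ~80% of the plateau
  i80 <- which(eta < 0.8 * eta_lo)[1]
  tau0 <- if (is.na(i80)) 1 / gdot[length(gdot) %/% 2] else 1 / gdot[i80]
  th0 <- c(log(eta_lo), log(tau0), log(1 - 0.5))
  best <- .multistart_lm(resid_fn, th0, n_starts = n_starts, spread = 0.7)
  th <- best$par
  k <- 3
  chi2r <- sum(best$fvec^2) / max(1, length(eta) - k)
  structure(list(eta0 = exp(th[1]), tau = exp(th[2]), p = 1 - exp(th[3]),
                 eta_inf = eta_inf, chi2_reduced = chi2r, flag = NA_character_,
                 converged = best$converged),
            class = "carreau_fit")
}

#' @export
print.carreau_fit <- function(x, ...) {
  if (identical(x$flag, "plateau_only")) {
    cat(sprintf("<carreau_fit> Newtonian plateau only: eta0 = %.4g Pa s\n",
                x$eta0))
  } else {
    cat(sprintf(
      "<carreau_fit> eta0 = %.4g Pa s, tau = %.4g s, p = %.3g (eta_inf = %g)\n",
      x$eta0, x$tau, x$p, x$eta_inf))
  }
  invisible(x)
}

#' Zero-shear viscosity of a flow curve
#'
#' For low-viscosity samples (`eta_sp_estimate` below `threshold`, default
#' 10) inertial instabilities at high shear can masquerade as thickening, so
#' the zero-shear viscosity is the mean viscosity over the detected
#' Newtonian plateau restricted to shear rates below `max_shear` (default
#' 100 1/s). For more viscous samples it is the Carreau `eta0`.
#'
#' @param curve A [flow_curve()].
#' @param eta_sp_estimate Rough specific-viscosity estimate used to select
#'   the branch.
#' @param threshold Branch threshold on `eta_sp_estimate`.
#' @param max_shear Upper shear-rate limit for the plateau average, 1/s.
#' @return Zero-shear viscosity, Pa s.
#' @export
zero_shear_viscosity <- function(curve, eta_sp_estimate, threshold = 10,
                                 max_shear = 100) {
  stopifnot(inherits(curve, "flow_curve"))
  if (eta_sp_estimate >= threshold) {
    return(carreau_fit(curve)$eta0)
  }
  keep <- curve$shear_rate < max_shear
  if (!any(keep)) stop("no points below the shear-rate limit")
  idx <- find_plateau(curve$shear_rate[keep], curve$viscosity[keep])
  mean(curve$viscosity[keep][idx])
}

#' Detect the Newtonian plateau of a flow curve
#'
#' Returns the indices of the longest low-shear run over which a local
#' log-log slope estimate (rolling 5-point regression on the
#' running-median-smoothed curve) stays within `slope_tol` of zero. Falls
#' back, with a warning, to the points within 2 % of the low-shear
#' viscosity if no run qualifies.
#'
#' @param shear_rate Shear rates, 1/s (increasing).
#' @param viscosity Viscosities, Pa s.
#' @param slope_tol Absolute log-log slope tolerance (default 0.02).
#' @return Integer indices of the plateau points.
#' @export
find_plateau <- function(shear_rate, viscosity, slope_tol = 0.02) {
  n <- length(shear_rate)
  if (n < 5) return(seq_len(n))
  lx <- log(shear_rate)
  ly <- log(stats::runmed(viscosity, k = min(5, n - (1 - n %% 2))))
  half <- 2L
  slopes <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    slopes[i] <- stats::coef(stats::lm(ly[j] ~ lx[j]))[2]
  }
  flat <- abs(slopes) <= slope_tol
  if (!any(flat)) {
    warning("no flat region found; falling back to low-shear points")
    return(which(viscosity >= 0.98 * exp(mean(ly[1:3]))))
  }
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]
  seq(starts[best], ends[best])
}

#' Relaxation time from the 90 % viscosity criterion
#'
#' The inverse of the shear rate at which the viscosity falls to 90 % of its
#' zero-shear value, evaluated on the fitted Carreau curve. For
#' `eta_inf = 0` the closed form is
#' `tau_90 = tau / sqrt(0.9^(2/(p-1)) - 1)`.
#'
#' @param fit_or_curve A `carreau_fit` or a [flow_curve()] (which is fitted
#'   first).
#' @param level Fractional viscosity level defining the relaxation time
#'   (default 0.9).
#' @return Relaxation time, s; `NA` with a warning if the curve never
#'   crosses the level (Newtonian).
#' @export
relaxation_time_90 <- function(fit_or_curve, level = 0.9) {
  fit <- if (inherits(fit_or_curve, "flow_curve")) {
    carreau_fit(fit_or_curve)
  } else {
    fit_or_curve
  }
  stopifnot(inherits(fit, "carreau_fit"))
  if (identical(fit$flag, "plateau_only") || !is.finite(fit$tau)) {
    warning("no shear thinning: relaxation time undefined")
    return(NA_real_)
  }
  r <- (level * fit$eta0 - fit$eta_inf) / (fit$eta0 - fit$eta_inf)
  if (r <= 0 || r >= 1) {
    warning("viscosity never reaches the requested level")
    return(NA_real_)
  }
  x2 <- r^(2 / (fit$p - 1)) - 1
  fit$tau / sqrt(x2)
}

#' Specific viscosity
#'
#' `(eta0 - eta_s) / eta_s` in the zero-shear limit. A negative value (a
#' solution apparently thinner than its solvent) is allowed but flagged
#' with a warning.
#'
#' @param eta0 Zero-shear viscosity of the solution, Pa s.
#' @param eta_s Solvent viscosity, Pa s.
#' @return Specific viscosity, dimensionless.
#' @export
specific_viscosity <- function(eta0, eta_s) {
  if (any(eta_s <= 0)) stop("eta_s must be positive")
  out <- (eta0 - eta_s) / eta_s
  if (any(out < 0)) warning("eta0 < eta_s: negative specific viscosity")
  out
}

#' Terminal modulus and thermal energy per chain
#'
#' `G = eta0 / tau`, and the modulus per chain number density in units of
#' `kB T`: `per_chain_energy = G M_w / (1000 c N_A kB T)` with `c` in g/L
#' (= kg/m^3).
#'
#' @param eta0 Zero-shear viscosity, Pa s.
#' @param tau Relaxation time, s.
#' @param concentration Polymer concentration, g/L.
#' @param M_w Weight-average molar mass, g/mol.
#' @param T Absolute temperature, K.
#' @return List with `G` (Pa) and `per_chain_energy` (multiples of kB T per
#'   chain).
#' @export
terminal_modulus <- function(eta0, tau, concentration, M_w, T = 298.15) {
  if (tau <= 0) stop("tau must be positive")
  if (concentration <= 0 || M_w <= 0 || T <= 0) stop("inputs must be positive")
  G <- eta0 / tau
  chains_per_m3 <- 1000 * concentration / M_w * .const$NA_
  list(G = G, per_chain_energy = G / (chains_per_m3 * .const$kB * T))
}

#' Per-sample rheology summary table
#'
#' Runs the per-sample analysis (Carreau fit, zero-shear viscosity,
#' specific viscosity, both relaxation times, terminal-modulus estimate) on
#' a list of flow curves and assembles the summary table consumed by the
#' regime segmentation.
#'
#' @param curves A list of [flow_curve()]s.
#' @param config A [run_config()] supplying the solvent viscosity, molar
#'   mass and temperature.
#' @return A data frame with one row per curve: `concentration`, `eta0`,
#'   `eta_sp`, `tau_carreau`, `tau_90`, `G_estimate`.
#' @export
rheo_summary <- function(curves, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  rows <- lapply(curves, function(cv) {
    fit <- carreau_fit(cv)
    eta_sp_rough <- specific_viscosity(fit$eta0, config$solvent_viscosity)
    eta0 <- zero_shear_viscosity(cv, eta_sp_rough)
    tau90 <- suppressWarnings(relaxation_time_90(fit))
    G <- if (is.finite(fit$tau)) eta0 / fit$tau else NA_real_
    data.frame(
      concentration = cv$concentration,
      eta0 = eta0,
      eta_sp = specific_viscosity(eta0, config$solvent_viscosity),
      tau_carreau = fit$tau,
      tau_90 = tau90,
      G_estimate = G
    )
  })
  do.call(rbind, rows)
}
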