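#' Initial guess for the correlation-peak position
#'
#' Fits and subtracts a `D q^(-3.6) + A/q + const` trend (upturn, rod-like
#' chain decay and flat background), smooths the remainder with a running
#' median, and returns the q of its interior maximum. Used only to anchor the stage-1 fit
#' window; the refined peak position comes from the fitted model. The
#' interior maximum must be significant relative to the point
#' uncertainties, otherwise a "peakless profile" error is raised.
#'
#' @param profile A [sans_profile()].
#' @param n_up Trend exponent (default 3.6).
#' @return Peak-position guess, 1/Angstrom.
#' @export
initial_qstar_guess <- function(profile, n_up = 3.6) {
  stopifnot(inherits(profile, "sans_profile"))
  q <- profile$q
  i <- profile$intensity
  n <- length(q)
  if (n < 10) stop("profile too short")
  X <- cbind(q^(-n_up), 1 / q, 1)
  cf <- stats::lm.fit(X, i)$coefficients
  resid <- i - X %*% cf
  k <- min(7L, n - (1 - n %% 2))
  z <- stats::runmed(as.numeric(resid), k = k)
  interior <- 3:(n - 2)
  i_max <- interior[which.max(z[interior])]
  thresh <- 3 * stats::median(profile$d_intensity)
  prominence <- z[i_max] - max(min(z[1:i_max]), min(z[i_max:n]))
  if (z[i_max] < thresh || prominence < thresh) {
    stop("peakless profile: no significant interior maximum")
  }
  q[i_max]
}

# Model evaluation with selected free parameters; `fixed` is a
# composite_params carrying the frozen values.
.eval_model <- function(q, fixed, free) {
  p <- fixed
  for (nm in names(free)) p[[nm]] <- free[[nm]]
  (p$I0 / q) * cross_section_factor(q, p$r_p) *
    peak_factor(q, p$peak_m, p$peak_d, p$peak_k) +
    p$S_inc + p$D_up * q^(-p$n_up)
}

.stage_result <- function(stage, params, profile, q_window, covariance,
                          converged, flag = NA_character_, n_free = 0) {
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2]
  r <- (composite_intensity(profile$q[sel], params) -
          profile$intensity[sel]) / profile$d_intensity[sel]
  chi2r <- sum(r^2) / max(1, sum(sel) - n_free)
  structure(list(stage = stage, params = params, chi2_reduced = chi2r,
                 q_window = q_window, covariance = covariance,
                 converged = converged, flag = flag),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("<stage_fit:%s> chi2_red = %.4g, window [%.4g, %.4g] 1/A%s\n",
              x$stage, x$chi2_reduced, x$q_window[1], x$q_window[2],
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  print(x$params)
  invisible(x)
}

#' Stage 1: fit the rigid-chain term on the high-q window
#'
#' Weighted (1/dI^2) least squares of the chain term on
#' `q > window_factor * qstar_guess`, where intermolecular interference is
#' negligible. Free parameters are `I0`, `r_p` and `S_inc`; `r_p` can be
#' frozen to a global value (e.g. the consensus 3.4 Angstrom) via
#' `r_p_fixed`. When a partially determined parameter set from a previous
#' pass is supplied via `known`, its peak and upturn components are kept
#' frozen in the model so the stage can be re-run self-consistently.
#'
#' @param profile A [sans_profile()].
#' @param qstar_guess Peak-position estimate anchoring the window,
#'   1/Angstrom.
#' @param window_factor Window starts at `window_factor * qstar_guess`.
#' @param r_p_fixed Optional frozen cross-section radius, Angstrom.
#' @param known Optional [composite_params()] carrying frozen peak/upturn
#'   components (defaults to none).
#' @param n_starts Multi-start count.
#' @return A `stage_fit` with stage `"high_q"`.
#' @export
fit_stage_high_q <- function(profile, qstar_guess, window_factor = 1.5,
                             r_p_fixed = NULL, known = NULL, n_starts = 10) {
  stopifnot(inherits(profile, "sans_profile"))
  q_lo <- window_factor * qstar_guess
  sel <- profile$q > q_lo
  if (sum(sel) < 15) {
    stop(sprintf("insufficient points above q = %.4g (%d < 15)",
                 q_lo, sum(sel)))
  }
  q <- profile$q[sel]
  y <- profile$intensity[sel]
  w <- 1 / profile$d_intensity[sel]
  fixed <- if (is.null(known)) {
    composite_params(I0 = 0, r_p = 1, S_inc = 0)
  } else {
    known
  }
  free_names <- if (is.null(r_p_fixed)) {
    c("I0", "r_p", "S_inc")
  } else {
    c("I0", "S_inc")
  }
  if (!is.null(r_p_fixed)) fixed$r_p <- r_p_fixed
  s0 <- max(min(y) * 0.9, 1e-8)
  i0 <- max((y[1] - s0) * q[1], 1e-8)
  th0 <- log(c(i0, if (is.null(r_p_fixed)) 3 else NULL, s0))
  resid_fn <- function(th) {
    fr <- as.list(exp(th))
    names(fr) <- free_names
    w * (.eval_model(q, fixed, fr) - y)
  }
  best <- .multistart_lm(resid_fn, th0, n_starts = n_starts)
  vals <- exp(best$par)
  names(vals) <- free_names
  params <- fixed
  for (nm in free_names) params[[nm]] <- unname(vals[[nm]])
  covariance <- .vcov_log_params(best, vals,
                                 length(q) - length(free_names))
  .stage_result("high_q", params, profile, c(q_lo, max(profile$q)),
                covariance, best$converged, n_free = length(free_names))
}

#' Stage 2: fit the correlation-peak multiplier
#'
#' Fits the peak shape parameters `m`, `d`, `k` on the window
#' `[0.3, window_factor] * qstar_guess` with the stage-1 chain parameters
#' (and any current upturn amplitude) frozen. If the weighted cost
#' improvement over the neutral factor is not significant, the fit is
#' flagged `"no_significant_peak"` and the neutral parameters returned.
#'
#' @param profile A [sans_profile()].
#' @param stage1 The `stage_fit` from [fit_stage_high_q()] (its params may
#'   carry a frozen `D_up` from a previous upturn pass).
#' @param qstar_guess Peak-position estimate, 1/Angstrom.
#' @param window_factor Upper window edge factor (matches stage 1's lower
#'   edge).
#' @param n_starts Multi-start count.
#' @return A `stage_fit` with stage `"peak"`.
#' @export
fit_stage_peak <- function(profile, stage1, qstar_guess,
                           window_factor = 1.5, n_starts = 10) {
  stopifnot(inherits(profile, "sans_profile"), inherits(stage1, "stage_fit"))
  win <- c(0.3, window_factor) * qstar_guess
  sel <- profile$q >= win[1] & profile$q <= win[2]
  if (sum(sel) < 10) {
    stop(sprintf("insufficient points in the peak window [%.4g, %.4g] (%d < 10)",
                 win[1], win[2], sum(sel)))
  }
  q <- profile$q[sel]
  y <- profile$intensity[sel]
  w <- 1 / profile$d_intensity[sel]
  fixed <- stage1$params
  base <- .eval_model(q, fixed, list(peak_m = 0))
  cost_null <- sum((w * (base - y))^2)
  m0 <- max(max(y / base) - 1, 0.3)
  th0 <- log(c(m0, qstar_guess, 0.2 * qstar_guess))
  resid_fn <- function(th) {
    fr <- list(peak_m = exp(th[1]), peak_d = exp(th[2]), peak_k = exp(th[3]))
    w * (.eval_model(q, fixed, fr) - y)
  }
  best <- .multistart_lm(resid_fn, th0, n_starts = n_starts)
  vals <- exp(best$par)
  flag <- NA_character_
  params <- fixed
  if (cost_null - best$cost < stats::qchisq(0.99, df = 3)) {
    flag <- "no_significant_peak"
    params$peak_m <- 0
    params$peak_d <- NA_real_
    params$peak_k <- NA_real_
    covariance <- NULL
  } else {
    params$peak_m <- vals[1]
    params$peak_d <- vals[2]
    params$peak_k <- vals[3]
    names(vals) <- c("peak_m", "peak_d", "peak_k")
    covariance <- .vcov_log_params(best, vals, length(q) - 3)
  }
  .stage_result("peak", params, profile, win, covariance, best$converged,
                flag = flag, n_free = 3)
}

#' Stage 3: fit the low-q upturn amplitude
#'
#' Fits the upturn amplitude `D_up` (exponent fixed at `n_up`) on the
#' window below the peak region, `q < low_factor * qstar_guess`, with all
#' other parameters frozen. The model is linear in `D_up`, so the weighted
#' least-squares solution is closed-form; the estimate is truncated at
#' zero. Fewer than 5 low-q points yield `D_up = 0` with flag
#' `"insufficient_low_q"`.
#'
#' @param profile A [sans_profile()].
#' @param stage2 The `stage_fit` from [fit_stage_peak()].
#' @param qstar_guess Peak-position estimate, 1/Angstrom.
#' @param n_up Upturn exponent (fixed, default 3.6).
#' @param low_factor Window ends at `low_factor * qstar_guess`.
#' @return A `stage_fit` with stage `"upturn"` whose params are the full
#'   [composite_params()].
#' @export
fit_stage_upturn <- function(profile, stage2, qstar_guess, n_up = 3.6,
                             low_factor = 0.3) {
  stopifnot(inherits(profile, "sans_profile"), inherits(stage2, "stage_fit"))
  q_hi <- low_factor * qstar_guess
  sel <- profile$q < q_hi
  params <- stage2$params
  params$n_up <- n_up
  if (sum(sel) < 5) {
    params$D_up <- 0
    return(.stage_result("upturn", params, profile,
                         c(min(profile$q), q_hi), NULL, TRUE,
                         flag = "insufficient_low_q", n_free = 1))
  }
  q <- profile$q[sel]
  y <- profile$intensity[sel]
  w <- 1 / profile$d_intensity[sel]^2
  base <- .eval_model(q, params, list(D_up = 0))
  u <- q^(-n_up)
  d_hat <- sum(w * (y - base) * u) / sum(w * u^2)
  params$D_up <- max(d_hat, 0)
  covariance <- matrix(1 / sum(w * u^2), 1, 1,
                       dimnames = list("D_up", "D_up"))
  .stage_result("upturn", params, profile, c(min(profile$q), q_hi),
                covariance, TRUE, n_free = 1)
}

#' Three-stage sequential fit of one SANS profile
#'
#' Runs the full staged procedure: (1) rigid-chain fit on the high-q
#' window anchored at `window_factor` times an initial peak-position
#' guess; (2) correlation-peak fit with the chain parameters frozen; (3)
#' closed-form upturn-amplitude fit. Stages 1-3 are then cycled, each with
#' the others' current estimates frozen in the model, until the parameter
#' vector is stationary; the stage-1 window is re-anchored whenever the
#' refined peak position moves its boundary by more than 10 %. On
#' correctly specified noiseless data this block-wise refinement converges
#' to the generating parameters.
#'
#' @param profile A [sans_profile()].
#' @param window_factor High-q window factor (default 1.5).
#' @param r_p_fixed Optional frozen cross-section radius, Angstrom.
#' @param n_up Upturn exponent (fixed).
#' @param n_starts Multi-start count for the first pass of each stage.
#' @param max_iter Maximum stage cycles.
#' @param tol Relative parameter-change convergence tolerance.
#' @return A list with `params` (final [composite_params()]), `stages`
#'   (the last `stage_fit` of each stage), `descriptor` (a
#'   [peak_descriptor()] or `NULL` if no significant peak),
#'   `qstar_guess`, `iterations`, `converged`.
#' @export
fit_sans_profile <- function(profile, window_factor = 1.5, r_p_fixed = NULL,
                             n_up = 3.6, n_starts = 10, max_iter = 12,
                             tol = 1e-8) {
  guess <- initial_qstar_guess(profile, n_up = n_up)
  qstar <- guess
  s1 <- fit_stage_high_q(profile, qstar, window_factor, r_p_fixed,
                         n_starts = n_starts)
  s2 <- NULL
  s3 <- NULL
  par_vec <- function(p) c(p$I0, p$r_p, p$S_inc, p$peak_m,
                           if (is.na(p$peak_d)) 0 else p$peak_d,
                           if (is.na(p$peak_k)) 0 else p$peak_k, p$D_up)
  prev <- par_vec(s1$params)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    ns <- if (it == 1) n_starts else 1
    s2 <- fit_stage_peak(profile, s1, qstar, window_factor, n_starts = ns)
    if (identical(s2$flag, "no_significant_peak")) break
    s3 <- fit_stage_upturn(profile, s2, qstar, n_up = n_up)
    # refined peak position from the fitted coherent curve
    desc <- peak_descriptor(s3$params)
    qstar_new <- desc$q_star
    if (abs(qstar_new - qstar) / qstar > 0.1) qstar <- qstar_new
    # multi-start again on the first re-pass: with the peak now frozen in the
    # model the chain parameters may sit in the wrong basin of the initial
    # peak-blind fit
    s1 <- fit_stage_high_q(profile, qstar, window_factor, r_p_fixed,
                           known = s3$params, n_starts = if (it <= 2) ns else 1)
    cur <- par_vec(s1$params)
    if (max(abs(cur - prev) / (abs(prev) + 1e-12)) < tol) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  params <- s1$params
  descriptor <- if (params$peak_m > 0) {
    peak_descriptor(params, data_q_range = range(profile$q))
  } else {
    NULL
  }
  list(params = params, stages = list(high_q = s1, peak = s2, upturn = s3),
       descriptor = descriptor, qstar_guess = guess, iterations = it,
       converged = converged)
}

#' Peak descriptors of a fitted composite model
#'
#' Measures the correlation peak on the coherent model curve (composite
#' minus background minus upturn): the peak position `q_star` is its
#' argmax, `I_q_star` is the full composite intensity there, and `fw75m`
#' is the full width where the coherent curve crosses 75 % of its maximum
#' (the 50 % level would require extrapolating deep into the
#' upturn-dominated region, so the 75 % width is the robust choice). A
#' crossing falling outside the supplied data range is flagged as
#' extrapolated.
#'
#' @param params A fitted [composite_params()] with a significant peak
#'   (`peak_m > 0`).
#' @param q_grid Evaluation grid, 1/Angstrom; defaults to a dense
#'   logarithmic grid spanning `[0.3, 3] * peak_d`.
#' @param data_q_range Optional `c(q_min, q_max)` of the underlying data,
#'   used only to flag extrapolated width crossings.
#' @param sharpness Function `(q_star, I_q_star, fw75m) -> number` defining
#'   the peak sharpness; defaults to `I_q_star / fw75m`.
#' @return An object of class `peak_descriptor`: list with `q_star`
#'   (1/Angstrom), `I_q_star` (1/cm), `fw75m` (1/Angstrom), `sharpness`,
#'   `flags` (character vector).
#' @export
peak_descriptor <- function(params, q_grid = NULL, data_q_range = NULL,
                            sharpness = NULL) {
  stopifnot(inherits(params, "composite_params"))
  if (params$peak_m <= 0) stop("no significant peak in params")
  if (is.null(q_grid)) {
    q_grid <- exp(seq(log(0.3 * params$peak_d), log(3 * params$peak_d),
                      length.out = 2001))
  }
  q_grid <- sort(q_grid)
  coh <- function(q) coherent_intensity(q, params)
  z <- coh(q_grid)
  i_max <- which.max(z)
  n <- length(q_grid)
  if (i_max == 1 || i_max == n) {
    stop("peak maximum not interior to the evaluation grid")
  }
  opt <- stats::optimize(coh, interval = c(q_grid[i_max - 1], q_grid[i_max + 1]),
                         maximum = TRUE, tol = 1e-12)
  q_star <- opt$maximum
  coh_max <- opt$objective
  flags <- character(0)
  target <- 0.75 * coh_max
  q_lo <- .level_crossing(coh, q_star, target, q_grid, side = "low")
  q_hi <- .level_crossing(coh, q_star, target, q_grid, side = "high")
  if (is.na(q_lo) || is.na(q_hi)) {
    flags <- c(flags, "width_unbracketed")
    fw <- NA_real_
  } else {
    fw <- q_hi - q_lo
    if (!is.null(data_q_range) &&
        (q_lo < data_q_range[1] || q_hi > data_q_range[2])) {
      flags <- c(flags, "width_extrapolated")
    }
  }
  I_q_star <- composite_intensity(q_star, params)
  sharp_fn <- if (is.null(sharpness)) {
    function(q_star, I_q_star, fw75m) I_q_star / fw75m
  } else {
    sharpness
  }
  structure(list(q_star = q_star, I_q_star = I_q_star, fw75m = fw,
                 sharpness = sharp_fn(q_star, I_q_star, fw),
                 flags = flags),
            class = "peak_descriptor")
}

#' @export
print.peak_descriptor <- function(x, ...) {
  cat(sprintf(
    "<peak_descriptor> q* = %.4g 1/A, I(q*) = %.4g 1/cm, FW75M = %.4g 1/A%s\n",
    x$q_star, x$I_q_star, x$fw75m,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' Power-law trend across a concentration series
#'
#' Least squares of `log(value)` on `log(c)`, with the exponent free or
#' fixed (e.g. to the scaling prediction 1/2). The prefactor is the fitted
#' value at c = 1 g/L.
#'
#' @param values Per-concentration quantity (positive).
#' @param concentrations Concentrations, g/L.
#' @param fixed_exponent Optional fixed exponent.
#' @return An object of class `series_trend`: list with `prefactor`,
#'   `exponent`, `exponent_fixed`, `residuals` (log space, data order) and
#'   `exponent_se` (free fits only).
#' @export
fit_series_trend <- function(values, concentrations, fixed_exponent = NULL) {
  if (length(values) != length(concentrations)) {
    stop("values and concentrations must have equal length")
  }
  if (length(values) < 3) stop("need at least 3 concentrations")
  if (any(values <= 0) || any(concentrations <= 0)) {
    stop("values and concentrations must be positive")
  }
  lx <- log(concentrations)
  ly <- log(values)
  if (is.null(fixed_exponent)) {
    fit <- stats::lm(ly ~ lx)
    cf <- stats::coef(fit)
    # summary() warns on exact power laws ("essentially perfect fit");
    # a zero standard error is the correct answer there
    se <- tryCatch(suppressWarnings(
      summary(fit)$coefficients["lx", "Std. Error"]),
      error = function(e) NA_real_)
    out <- list(prefactor = exp(unname(cf[1])), exponent = unname(cf[2]),
                exponent_fixed = FALSE,
                residuals = unname(stats::residuals(fit)),
                exponent_se = unname(se))
  } else {
    a <- mean(ly - fixed_exponent * lx)
    out <- list(prefactor = exp(a), exponent = fixed_exponent,
                exponent_fixed = TRUE,
                residuals = ly - a - fixed_exponent * lx,
                exponent_se = NA_real_)
  }
  structure(out, class = "series_trend")
}

#' @export
print.series_trend <- function(x, ...) {
  cat(sprintf("<series_trend> value = %.4g * c^%.4g%s\n", x$prefactor,
              x$exponent, if (x$exponent_fixed) " (exponent fixed)" else ""))
  invisible(x)
}

#' Consistency regressions of the stage-1 amplitudes
#'
#' The incoherent background should be proportional to the monomer volume
#' fraction `phi` and the chain-term amplitude to `phi (1 - phi)`, both
#' through the origin. Given a theoretical amplitude-per-volume-fraction
#' constant (from contrast factors), the shortfall of the measured slope
#' yields the residual water mass fraction of the dry polymer,
#' `1 - slope_measured / slope_theoretical`.
#'
#' @param I0 Per-concentration chain-term amplitudes.
#' @param S_inc Per-concentration incoherent backgrounds, 1/cm.
#' @param volume_fractions Monomer volume fractions (from the nominal
#'   concentrations).
#' @param theoretical_I0_slope Optional theoretical `I0` per unit
#'   `phi (1 - phi)`.
#' @return A list with `S_inc_slope`, `S_inc_r2`, `I0_slope`, `I0_r2` and
#'   (if the theoretical slope is given) `water_mass_fraction`.
#' @export
consistency_regressions <- function(I0, S_inc, volume_fractions,
                                    theoretical_I0_slope = NULL) {
  phi <- volume_fractions
  if (length(I0) < 3 || length(S_inc) != length(I0) ||
      length(phi) != length(I0)) {
    stop("need >= 3 concentrations with matching I0, S_inc, volume_fractions")
  }
  if (stats::sd(phi) == 0) stop("degenerate volume fractions")
  through_origin <- function(y, x) {
    slope <- sum(x * y) / sum(x^2)
    r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
    list(slope = slope, r2 = r2)
  }
  fs <- through_origin(S_inc, phi)
  fi <- through_origin(I0, phi * (1 - phi))
  out <- list(S_inc_slope = fs$slope, S_inc_r2 = fs$r2,
              I0_slope = fi$slope, I0_r2 = fi$r2)
  if (!is.null(theoretical_I0_slope)) {
    out$water_mass_fraction <- 1 - fi$slope / theoretical_I0_slope
  }
  out
}

#' Wald-Wolfowitz runs test on the signs of a sequence
#'
#' Two-sided normal-approximation p-value for the number of sign runs;
#' used as a structure diagnostic on fit residuals (few runs indicate
#' curvature or a misspecified model).
#'
#' @param x Numeric sequence (typically ordered residuals); zeros are
#'   dropped.
#' @return p-value.
#' @export
sign_runs_test <- function(x) {
  s <- sign(x[x != 0])
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(1)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  z <- (runs - mu) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

# Walk outward from the peak until f drops below `target`, extending the
# search grid once if needed, then polish the crossing with uniroot.
.level_crossing <- function(f, q_star, target, q_grid, side) {
  if (side == "low") {
    qq <- rev(q_grid[q_grid < q_star])
    ext <- function(qmin) rev(exp(seq(log(qmin / 4), log(qmin),
                                      length.out = 200)))
  } else {
    qq <- q_grid[q_grid > q_star]
    ext <- function(qmax) exp(seq(log(qmax), log(qmax * 4),
                                  length.out = 200))
  }
  for (pass in 1:2) {
    zz <- f(qq)
    below <- which(zz < target)
    if (length(below)) {
      j <- below[1]
      br <- sort(c(qq[j], if (j > 1) qq[j - 1] else q_star))
      return(stats::uniroot(function(q) f(q) - target, br, tol = 1e-12)$root)
    }
    qq <- ext(if (side == "low") min(qq) else max(qq))
  }
  NA_real_
}

# Covariance of exp-transformed parameters via the delta method; the
# nls.lm hessian approximates J'J of the weighted residuals.
.vcov_log_params <- function(fit, vals, dof) {
  tryCatch({
    chi2r <- fit$cost / max(1, dof)
    v_log <- solve(fit$hessian) * chi2r
    D <- diag(as.numeric(vals), nrow = length(vals))
    v <- D %*% v_log %*% D
    dimnames(v) <- list(names(vals), names(vals))
    v
  }, error = function(e) NULL)
}
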