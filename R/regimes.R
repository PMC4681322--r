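#' Segment a concentration series into continuous power-law regimes
#'
#' Fits `log(eta_sp)` vs `log(c)` with a continuous piecewise-linear model
#' of up to three segments (semidilute unentangled, entangled,
#' concentrated). Breakpoints are found by an exhaustive grid over the
#' inter-point gaps followed by Nelder-Mead refinement; slopes are either
#' free or fixed to the scaling predictions (0.5, 1.5, 3.75). Continuity at
#' the breakpoints is enforced, so the crossovers are the intersections of
#' the straight lines in log-log space.
#'
#' @param c Concentrations, g/L.
#' @param eta_sp Specific viscosities (or any positive quantity with
#'   piecewise power-law behaviour).
#' @param mode `"free"` (slopes fitted) or `"fixed_scaling"` (slopes fixed
#'   to `fixed_slopes`).
#' @param fixed_slopes Scaling slopes used in `fixed_scaling` mode.
#' @param n_segments Number of segments to fit (1-3, default 3). If the
#'   data cannot support the requested number (fewer than 3 points per
#'   segment), the largest supported number is fitted and flagged.
#' @param min_per_segment Minimum points per segment (default 2: with
#'   continuity enforced each additional segment contributes one slope
#'   degree of freedom, so two interior points determine it).
#' @return An object of class `regime_summary`: list with `slopes`,
#'   `prefactors` (segment values extrapolated to c = 1 g/L), `breaks`
#'   (crossover concentrations, g/L), `c_e`, `c_D`, `c_star_viscosity`
#'   (extrapolation of the first segment to `eta_sp = 1`), `mode`, `sse`,
#'   `n_segments`, `flag`.
#' @export
fit_piecewise_powerlaws <- function(c, eta_sp,
                                    mode = c("free", "fixed_scaling"),
                                    fixed_slopes = c(0.5, 1.5, 3.75),
                                    n_segments = 3, min_per_segment = 2) {
  mode <- match.arg(mode)
  if (any(c <= 0) || any(eta_sp <= 0)) stop("c and eta_sp must be positive")
  ord <- order(c)
  x <- log(c[ord])
  y <- log(eta_sp[ord])
  n <- length(x)
  flag <- NA_character_
  k_max <- max(1, n %/% min_per_segment)
  if (n_segments > k_max) {
    flag <- sprintf("only %d segment(s) supported by %d points", k_max, n)
    warning(flag)
    n_segments <- k_max
  }
  slopes_fix <- if (mode == "fixed_scaling") fixed_slopes[seq_len(n_segments)] else NULL

  fit_at <- function(brk) {
    # least squares of the continuous piecewise-linear model at fixed breaks
    X <- cbind(1, x)
    for (b in brk) X <- cbind(X, pmax(x - b, 0))
    if (is.null(slopes_fix)) {
      cf <- stats::lm.fit(X, y)$coefficients
      resid <- y - X %*% cf
      list(sse = sum(resid^2), coef = cf)
    } else {
      inc <- c(slopes_fix[1], diff(slopes_fix))
      yadj <- y - X[, -1, drop = FALSE] %*% inc
      a <- mean(yadj)
      resid <- yadj - a
      list(sse = sum(resid^2), coef = c(a, inc))
    }
  }

  if (n_segments == 1) {
    fit <- fit_at(numeric(0))
    brk <- numeric(0)
  } else {
    # candidate breaks at gap midpoints, leaving min_per_segment per side
    mids <- (x[-1] + x[-n]) / 2
    lo <- min_per_segment
    cand <- mids[seq(lo, n - lo)]
    combos <- if (n_segments == 2) {
      matrix(cand, ncol = 1)
    } else {
      cc <- expand.grid(b1 = cand, b2 = cand)
      # keep pairs in order with room for the middle segment
      idx1 <- match(cc$b1, mids)
      idx2 <- match(cc$b2, mids)
      as.matrix(cc[idx2 - idx1 >= min_per_segment, , drop = FALSE])
    }
    sses <- apply(combos, 1, function(b) fit_at(b)$sse)
    brk0 <- combos[which.min(sses), ]
    obj <- function(b) {
      b <- sort(b)
      cnt <- findInterval(x, b)
      if (any(tabulate(cnt + 1, nbins = n_segments) < min_per_segment)) {
        return(1e10)
      }
      fit_at(b)$sse
    }
    opt <- if (length(brk0) == 1) {
      stats::optim(brk0, obj, method = "Brent", lower = min(x),
                   upper = max(x), control = list(reltol = 1e-14))
    } else {
      stats::optim(brk0, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 2000))
    }
    brk <- unname(sort(opt$par))
    fit <- fit_at(brk)
  }

  cf <- fit$coef
  a <- unname(cf[1])
  inc <- cf[-1]
  slopes <- unname(cumsum(inc))
  # value of each segment's straight line extrapolated to log c = 0
  icpt <- a
  prefactors <- numeric(n_segments)
  prefactors[1] <- exp(icpt)
  if (n_segments > 1) {
    for (j in 2:n_segments) {
      icpt <- icpt + (slopes[j - 1] - slopes[j]) * brk[j - 1]
      prefactors[j] <- exp(icpt)
    }
  }
  breaks_c <- unname(exp(brk))
  structure(list(
    slopes = unname(as.numeric(slopes)),
    prefactors = unname(prefactors),
    breaks = unname(breaks_c),
    c_e = if (n_segments >= 2) breaks_c[1] else NA_real_,
    c_D = if (n_segments >= 3) breaks_c[2] else NA_real_,
    c_star_viscosity = overlap_from_viscosity(prefactors[1], slopes[1]),
    mode = mode, sse = fit$sse, n_segments = n_segments, flag = flag
  ), class = "regime_summary")
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf(
    "<regime_summary> %d segment(s) [%s]: slopes %s; crossovers %s g/L; c* = %.3g g/L\n",
    x$n_segments, x$mode,
    paste(sprintf("%.3g", x$slopes), collapse = ", "),
    if (length(x$breaks)) paste(sprintf("%.3g", x$breaks), collapse = ", ")
    else "none",
    x$c_star_viscosity))
  invisible(x)
}

#' Overlap concentration from the unentangled viscosity power law
#'
#' Extrapolates the first-segment power law `eta_sp = prefactor * c^slope`
#' to `eta_sp = 1`: `c* = prefactor^(-1/slope)`.
#'
#' @param prefactor_first_segment First-segment specific viscosity at
#'   c = 1 g/L.
#' @param slope_first_segment First-segment exponent (positive).
#' @return Overlap concentration, g/L.
#' @export
overlap_from_viscosity <- function(prefactor_first_segment,
                                   slope_first_segment) {
  if (slope_first_segment <= 0) stop("slope must be positive")
  if (prefactor_first_segment <= 0) stop("prefactor must be positive")
  prefactor_first_segment^(-1 / slope_first_segment)
}

#' Relaxation-time exponents below and above a crossover
#'
#' Separate log-log slopes of the relaxation time versus concentration on
#' each side of `break_at` (typically `c_D`). A side with fewer than 3
#' points returns `NA` for that slope.
#'
#' @param c Concentrations, g/L.
#' @param tau_values Relaxation times, s.
#' @param break_at Crossover concentration, g/L.
#' @return Named numeric vector `c(low_c_exponent, high_c_exponent)`.
#' @export
tau_regime_exponents <- function(c, tau_values, break_at) {
  ok <- is.finite(c) & is.finite(tau_values) & c > 0 & tau_values > 0
  c <- c[ok]
  tau_values <- tau_values[ok]
  lo <- c < break_at
  slope_of <- function(cc, tt) {
    if (length(cc) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(log(tt) ~ log(cc)))[2])
  }
  c(low_c_exponent = slope_of(c[lo], tau_values[lo]),
    high_c_exponent = slope_of(c[!lo], tau_values[!lo]))
}
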