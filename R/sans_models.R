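#' Composite SANS intensity model parameters
#'
#' Parameters of the composite intensity model for a semidilute salt-free
#' polyelectrolyte solution,
#' \deqn{I(q) = \frac{I_0}{q}\left[\frac{2 J_1(q r_p)}{q r_p}\right]^2
#'   P(q) + S_{inc} + D q^{-n},}
#' i.e. a locally rigid (wormlike) chain with circular cross-section of
#' radius `r_p`, an empirical correlation-peak multiplier `P(q)` (see
#' [peak_factor()]), a flat incoherent background, and an additive low-q
#' power-law upturn. `I_0` absorbs contrast, concentration and monomer
#' length; no physical meaning is assigned to the peak shape parameters.
#'
#' @param I0 Intensity scale of the chain term, 1/cm * 1/Angstrom^-1
#'   (i.e. `I0/q` is in 1/cm for `q` in 1/Angstrom). Non-negative.
#' @param r_p Cross-section radius, Angstrom. Positive.
#' @param S_inc Incoherent (flat) background, 1/cm. Non-negative.
#' @param peak_m Peak amplitude; `0` is the neutral value (factor
#'   identically 1). Non-negative.
#' @param peak_d Peak position parameter, 1/Angstrom. Required positive when
#'   `peak_m > 0`.
#' @param peak_k Peak width parameter, 1/Angstrom. Required positive when
#'   `peak_m > 0`.
#' @param D_up Upturn amplitude, 1/cm * Angstrom^-n_up. Non-negative.
#' @param n_up Upturn exponent; fixed at 3.6 by default.
#' @return An object of class `composite_params`.
#' @export
composite_params <- function(I0, r_p, S_inc, peak_m = 0, peak_d = NA_real_,
                             peak_k = NA_real_, D_up = 0, n_up = 3.6) {
  p <- list(I0 = as.numeric(I0), r_p = as.numeric(r_p),
            S_inc = as.numeric(S_inc), peak_m = as.numeric(peak_m),
            peak_d = as.numeric(peak_d), peak_k = as.numeric(peak_k),
            D_up = as.numeric(D_up), n_up = as.numeric(n_up))
  if (!is.finite(p$I0) || p$I0 < 0) stop("I0 must be non-negative")
  if (!is.finite(p$r_p) || p$r_p <= 0) stop("r_p must be positive")
  if (!is.finite(p$S_inc) || p$S_inc < 0) stop("S_inc must be non-negative")
  if (!is.finite(p$peak_m) || p$peak_m < 0) stop("peak_m must be non-negative")
  if (p$peak_m > 0 &&
      (!is.finite(p$peak_d) || p$peak_d <= 0 ||
       !is.finite(p$peak_k) || p$peak_k <= 0)) {
    stop("peak_d and peak_k must be positive when peak_m > 0")
  }
  if (!is.finite(p$D_up) || p$D_up < 0) stop("D_up must be non-negative")
  if (!is.finite(p$n_up) || p$n_up <= 0) stop("n_up must be positive")
  structure(p, class = "composite_params")
}

#' @export
print.composite_params <- function(x, ...) {
  cat(sprintf(
    paste0("<composite_params> I0 = %.4g, r_p = %.3g A, S_inc = %.4g 1/cm, ",
           "peak (m, d, k) = (%.3g, %.4g, %.4g), D_up = %.3g, n_up = %.3g\n"),
    x$I0, x$r_p, x$S_inc, x$peak_m, x$peak_d, x$peak_k, x$D_up, x$n_up))
  invisible(x)
}

#' Circular cross-section form factor of a rigid chain
#'
#' `[2 J1(q r_p) / (q r_p)]^2`, the normalised cross-section factor of a
#' homogeneous (step-density) circular cylinder of radius `r_p`. Tends to 1
#' as `q r_p -> 0` (the limit is handled analytically) and is bounded above
#' by 1.
#'
#' @param q Momentum transfer, 1/Angstrom. Positive.
#' @param r_p Cross-section radius, Angstrom. Positive.
#' @return Dimensionless factor in `[0, 1]`.
#' @export
cross_section_factor <- function(q, r_p) {
  if (any(q <= 0)) stop("q must be positive")
  if (!is.finite(r_p) || r_p <= 0) stop("r_p must be positive")
  x <- q * r_p
  out <- numeric(length(x))
  small <- x < 1e-6
  big <- x > 1e4
  mid <- !small & !big
  # 2 J1(x)/x = 1 - x^2/8 + O(x^4): squared, 1 - x^2/4 suffices below 1e-6
  out[small] <- 1 - x[small]^2 / 4
  out[mid] <- (2 * besselJ(x[mid], 1) / x[mid])^2
  # large-argument asymptote, J1(x) ~ sqrt(2/(pi x)) cos(x - 3 pi/4)
  xb <- x[big]
  out[big] <- (2 * sqrt(2 / (pi * xb)) * cos(xb - 3 * pi / 4) / xb)^2
  out
}

#' Rigid-chain (high-q) intensity term
#'
#' `(I0/q) * cross_section_factor(q, r_p) + S_inc`: the rod-like asymptote of
#' a wormlike chain with circular cross-section plus the flat incoherent
#' background. This is the model fitted to the high-q window where
#' intermolecular interference is negligible.
#'
#' @inheritParams cross_section_factor
#' @param I0 Intensity scale (see [composite_params()]).
#' @param S_inc Incoherent background, 1/cm.
#' @return Intensity, 1/cm.
#' @export
chain_term <- function(q, I0, r_p, S_inc) {
  if (any(q <= 0)) stop("q must be positive")
  (I0 / q) * cross_section_factor(q, r_p) + S_inc
}

#' Empirical correlation-peak multiplier
#'
#' A descriptive interchain structure-factor stand-in,
#' \deqn{P(q) = \frac{1 + m\,e^{-(q-d)^2/(2k^2)}}{1 + m\,(d/2q)^4}.}
#' The numerator carries the correlation peak; the denominator suppresses
#' the factor at `q` well below the peak, where interchain interference
#' screens the rod-like single-chain scattering (`P ~ q^4` as `q -> 0`,
#' so the coherent product falls instead of following the 1/q chain
#' term). The factor is positive, tends to 1 at large `q` (leaving the
#' high-q chain fit unperturbed), has at most one local maximum, and
#' reduces to the neutral factor 1 at `m = 0`. No physical meaning is
#' attached to `m`, `d`, `k`; they only parameterise the position, height
#' and width of the correlation peak.
#'
#' @param q Momentum transfer, 1/Angstrom.
#' @param peak_m Amplitude, `>= 0`; `0` is neutral.
#' @param peak_d Position parameter, 1/Angstrom.
#' @param peak_k Width parameter, 1/Angstrom.
#' @return Dimensionless positive factor.
#' @export
peak_factor <- function(q, peak_m, peak_d, peak_k) {
  if (!is.finite(peak_m) || peak_m < 0) stop("peak_m must be non-negative")
  if (peak_m == 0) return(rep(1, length(q)))
  if (!is.finite(peak_d) || peak_d <= 0 || !is.finite(peak_k) || peak_k <= 0) {
    stop("peak_d and peak_k must be positive")
  }
  (1 + peak_m * exp(-(q - peak_d)^2 / (2 * peak_k^2))) /
    (1 + peak_m * (peak_d / (2 * q))^4)
}

#' Low-q power-law upturn
#'
#' `D_up * q^(-n_up)`. Cluster-like excess scattering at low q, fitted with
#' the exponent fixed (3.6 by default) and only the amplitude free.
#'
#' @param q Momentum transfer, 1/Angstrom. Positive.
#' @param D_up Amplitude, 1/cm * Angstrom^-n_up. Non-negative.
#' @param n_up Exponent, positive.
#' @return Intensity, 1/cm.
#' @export
upturn_term <- function(q, D_up, n_up = 3.6) {
  if (any(q <= 0)) stop("q must be positive")
  D_up * q^(-n_up)
}

#' Evaluate the composite intensity model
#'
#' The peak multiplier applies to the coherent chain term only; the
#' incoherent background and the upturn are additive outside the product.
#'
#' @param q Momentum transfer, 1/Angstrom. Positive.
#' @param params A [composite_params()].
#' @return Intensity, 1/cm.
#' @export
composite_intensity <- function(q, params) {
  stopifnot(inherits(params, "composite_params"))
  (params$I0 / q) * cross_section_factor(q, params$r_p) *
    peak_factor(q, params$peak_m, params$peak_d, params$peak_k) +
    params$S_inc + upturn_term(q, params$D_up, params$n_up)
}

#' Coherent chain + peak part of the composite model
#'
#' The composite intensity with background and upturn removed; the curve on
#' which the peak position, height and width are measured.
#'
#' @inheritParams composite_intensity
#' @return Intensity, 1/cm.
#' @export
coherent_intensity <- function(q, params) {
  stopifnot(inherits(params, "composite_params"))
  (params$I0 / q) * cross_section_factor(q, params$r_p) *
    peak_factor(q, params$peak_m, params$peak_d, params$peak_k)
}
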