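# Independent numerical oracles used across the suite.

# First-order Bessel function of the first kind via its 30-term power
# series; independent of base besselJ.
bessel_j1_series <- function(x, terms = 30) {
  out <- 0
  for (k in 0:(terms - 1)) {
    out <- out + (-1)^k / (factorial(k) * factorial(k + 1)) * (x / 2)^(2 * k + 1)
  }
  out
}

cross_section_oracle <- function(q, r_p) {
  x <- q * r_p
  (2 * bessel_j1_series(x) / x)^2
}

# Log-log slope of y(x) by ordinary least squares.
loglog_slope <- function(x, y) {
  unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])
}

# A noiseless single-concentration profile plus its generating parameters.
make_noiseless_profile <- function(concentration = 10, ...) {
  spec <- sans_series_spec(concentrations = concentration,
                           noise_fraction = 0, ...)
  prof <- generate_sans_series(spec)
  list(profile = prof[[1]], truth = attr(prof, "truth")[[1]], spec = spec)
}
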