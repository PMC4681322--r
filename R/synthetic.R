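#' Specification of a synthetic SANS concentration series
#'
#' Defines the ground truth for a simulated concentration series of a
#' salt-free polyelectrolyte (carboxymethyl cellulose-like) solution: a
#' correlation peak at `q* = qstar_prefactor * sqrt(c)`, a rigid-chain
#' term with cross-section radius `r_p`, an incoherent background
#' proportional to the monomer volume fraction, a chain-term amplitude
#' proportional to `phi (1 - phi)`, and a low-q power-law upturn growing
#' with concentration. A residual water fraction in the nominal polymer
#' scales all intensity amplitudes down by `1 - water_mass_fraction`,
#' emulating concentrations made up from an incompletely dried powder.
#'
#' @param concentrations Nominal concentrations, g/L (default 8 log-spaced
#'   values, 4-40 g/L).
#' @param qstar_prefactor Peak-position prefactor, 1/Angstrom (g/L)^(-1/2).
#' @param r_p Cross-section radius, Angstrom.
#' @param upturn_exponent Upturn power-law exponent.
#' @param upturn_per_conc Upturn amplitude per unit (corrected)
#'   concentration, 1/cm Angstrom^-n (g/L)^-1.
#' @param i0_per_phi Chain-term amplitude per unit `phi (1 - phi)`.
#' @param sinc_per_phi Incoherent background per unit volume fraction, 1/cm.
#' @param specific_volume Monomer specific volume, L/g (converts
#'   concentration to volume fraction).
#' @param peak_amplitude Peak multiplier amplitude `m`.
#' @param peak_rel_width Peak width parameter `k` as a fraction of `q*`.
#' @param water_mass_fraction Residual water mass fraction, `[0, 1)`.
#' @param noise_fraction Relative 1-sigma Gaussian noise (0.02 default).
#' @param q_grid Momentum-transfer grid, 1/Angstrom (150 log-spaced points
#'   over 0.003-0.6 by default).
#' @param seed Integer seed (mandatory; generation never touches the
#'   global RNG stream).
#' @return An object of class `sans_series_spec`.
#' @export
sans_series_spec <- function(concentrations = exp(seq(log(4), log(40),
                                                      length.out = 8)),
                             qstar_prefactor = 0.021,
                             r_p = 3.4,
                             upturn_exponent = 3.6,
                             upturn_per_conc = 1e-9,
                             i0_per_phi = 1.7,
                             sinc_per_phi = 20,
                             specific_volume = 6e-4,
                             peak_amplitude = 4,
                             peak_rel_width = 0.15,
                             water_mass_fraction = 0.18,
                             noise_fraction = 0.02,
                             q_grid = exp(seq(log(0.003), log(0.6),
                                              length.out = 150)),
                             seed = 1L) {
  spec <- list(concentrations = sort(as.numeric(concentrations)),
               qstar_prefactor = qstar_prefactor, r_p = r_p,
               upturn_exponent = upturn_exponent,
               upturn_per_conc = upturn_per_conc,
               i0_per_phi = i0_per_phi, sinc_per_phi = sinc_per_phi,
               specific_volume = specific_volume,
               peak_amplitude = peak_amplitude,
               peak_rel_width = peak_rel_width,
               water_mass_fraction = water_mass_fraction,
               noise_fraction = noise_fraction,
               q_grid = sort(as.numeric(q_grid)), seed = as.integer(seed))
  pos <- c("qstar_prefactor", "r_p", "upturn_exponent",
           "i0_per_phi", "sinc_per_phi", "specific_volume",
           "peak_amplitude", "peak_rel_width")
  for (f in pos) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0) {
      stop(sprintf("%s must be positive", f))
    }
  }
  if (!is.finite(spec$upturn_per_conc) || spec$upturn_per_conc < 0) {
    stop("upturn_per_conc must be non-negative")
  }
  if (any(spec$concentrations <= 0)) stop("concentrations must be positive")
  if (spec$water_mass_fraction < 0 || spec$water_mass_fraction >= 1) {
    stop("water_mass_fraction must be in [0, 1)")
  }
  if (spec$noise_fraction < 0) stop("noise_fraction must be non-negative")
  qs <- spec$qstar_prefactor * sqrt(spec$concentrations)
  qr <- range(spec$q_grid)
  if (any(qs <= qr[1]) || any(1.5 * qs >= qr[2])) {
    stop("peak positions (and their 1.5x windows) must lie inside q_grid")
  }
  structure(spec, class = "sans_series_spec")
}

# Solve the peak position parameter d so the coherent curve's argmax lands
# exactly on q_target: the chain decay and the low-q suppression both shift
# the maximum off d, so the stationarity condition is solved numerically on
# the full coherent log-curve (robust to changes of the peak-factor form).
.solve_peak_d <- function(q_target, m, k, r_p) {
  f <- function(d) {
    h <- q_target * 1e-6
    coh <- function(q) {
      log(cross_section_factor(q, r_p) / q * peak_factor(q, m, d, k))
    }
    (coh(q_target + h) - coh(q_target - h)) / (2 * h)
  }
  dd <- seq(0.3 * q_target, q_target + 6 * k, length.out = 500)
  fv <- vapply(dd, f, numeric(1))
  j <- which(fv[-1] * fv[-length(fv)] <= 0)[1]
  if (is.na(j)) {
    stop("no peak parameter places the coherent maximum at the target")
  }
  stats::uniroot(f, c(dd[j], dd[j + 1]), tol = 1e-14)$root
}

#' Ground-truth composite parameters for one synthetic concentration
#'
#' @param spec A [sans_series_spec()].
#' @param c_nominal Nominal concentration, g/L.
#' @return A [composite_params()] carrying the generating truth.
#' @export
synthetic_sans_params <- function(spec, c_nominal) {
  stopifnot(inherits(spec, "sans_series_spec"))
  c_true <- correct_concentration(c_nominal, spec$water_mass_fraction)
  phi <- spec$specific_volume * c_true
  q_star <- spec$qstar_prefactor * sqrt(c_nominal)
  k <- spec$peak_rel_width * q_star
  d <- .solve_peak_d(q_star, spec$peak_amplitude, k, spec$r_p)
  composite_params(
    I0 = spec$i0_per_phi * phi * (1 - phi),
    r_p = spec$r_p,
    S_inc = spec$sinc_per_phi * phi,
    peak_m = spec$peak_amplitude, peak_d = d, peak_k = k,
    D_up = spec$upturn_per_conc * c_true,
    n_up = spec$upturn_exponent
  )
}

#' Generate a synthetic SANS concentration series
#'
#' Evaluates the composite model for each concentration on the spec's q
#' grid and adds independent Gaussian noise with relative standard
#' deviation `noise_fraction`; the per-point uncertainty `dI` is set to
#' that standard deviation (floored at `1e-8 * I` so zero-noise profiles
#' remain valid). Byte-identical output for a fixed seed.
#'
#' @param spec A [sans_series_spec()].
#' @return A list of [sans_profile()]s (nominal concentrations in the
#'   metadata) with attribute `truth`: a list of the generating
#'   [composite_params()] plus the target `q_star` per concentration.
#' @export
generate_sans_series <- function(spec) {
  stopifnot(inherits(spec, "sans_series_spec"))
  q <- spec$q_grid
  truth <- list()
  profiles <- withr::with_seed(spec$seed, {
    lapply(spec$concentrations, function(cc) {
      pars <- synthetic_sans_params(spec, cc)
      model <- composite_intensity(q, pars)
      sigma <- spec$noise_fraction * model
      noisy <- model + stats::rnorm(length(q), 0, sigma)
      truth[[length(truth) + 1]] <<- list(
        concentration = cc, params = pars,
        q_star = spec$qstar_prefactor * sqrt(cc)
      )
      sans_profile(q, noisy, pmax(sigma, 1e-8 * model), concentration = cc,
                   instrument_label = "synthetic")
    })
  })
  attr(profiles, "truth") <- truth
  profiles
}

#' Specification of a synthetic steady-shear concentration series
#'
#' Ground truth for simulated flow curves: the zero-shear specific
#' viscosity follows a continuous three-segment power law in
#' concentration (semidilute unentangled / entangled / concentrated)
#' anchored at `eta_sp_anchor`, the Carreau relaxation time is constant
#' below the concentrated crossover and grows as `c^3` above it, and
#' each curve is a Carreau profile with multiplicative Gaussian noise.
#'
#' @param concentrations Concentrations, g/L (default 12 log-spaced,
#'   0.2-40).
#' @param regime_slopes Power-law exponents of the three regimes.
#' @param breaks Crossover concentrations `c(c_e, c_D)`, g/L.
#' @param eta_sp_anchor `c(concentration, eta_sp)` pin fixing the absolute
#'   level of the first segment.
#' @param tau0 Relaxation time below the concentrated crossover, s.
#' @param carreau_p Carreau shear-thinning exponent.
#' @param solvent_viscosity Solvent viscosity, Pa s.
#' @param noise_fraction Relative 1-sigma multiplicative noise.
#' @param shear_rate_grid Shear-rate grid, 1/s.
#' @param seed Integer seed.
#' @return An object of class `rheo_series_spec`.
#' @export
rheo_series_spec <- function(concentrations = exp(seq(log(0.2), log(40),
                                                      length.out = 12)),
                             regime_slopes = c(0.68, 1.7, 3.4),
                             breaks = c(4, 14.3),
                             eta_sp_anchor = c(0.07, 1),
                             tau0 = 0.05,
                             carreau_p = 0.5,
                             solvent_viscosity = 8.9e-4,
                             noise_fraction = 0.01,
                             shear_rate_grid = exp(seq(log(0.01), log(800),
                                                       length.out = 40)),
                             seed = 1L) {
  spec <- list(concentrations = sort(as.numeric(concentrations)),
               regime_slopes = as.numeric(regime_slopes),
               breaks = sort(as.numeric(breaks)),
               eta_sp_anchor = as.numeric(eta_sp_anchor),
               tau0 = tau0, carreau_p = carreau_p,
               solvent_viscosity = solvent_viscosity,
               noise_fraction = noise_fraction,
               shear_rate_grid = sort(as.numeric(shear_rate_grid)),
               seed = as.integer(seed))
  if (any(spec$concentrations <= 0)) stop("concentrations must be positive")
  if (length(spec$regime_slopes) != length(spec$breaks) + 1) {
    stop("need one more slope than breaks")
  }
  if (any(spec$breaks <= 0)) stop("breaks must be positive")
  if (length(spec$eta_sp_anchor) != 2 || any(spec$eta_sp_anchor <= 0)) {
    stop("eta_sp_anchor must be a positive (concentration, eta_sp) pair")
  }
  if (spec$tau0 <= 0 || spec$carreau_p >= 1 ||
      spec$solvent_viscosity <= 0 || spec$noise_fraction < 0) {
    stop("invalid rheology spec parameters")
  }
  structure(spec, class = "rheo_series_spec")
}

#' Piecewise power-law specific viscosity of a synthetic series
#'
#' Continuous piecewise power law through the anchor point; exported so
#' tests and analyses can evaluate the generator's ground truth directly.
#'
#' @param c Concentrations, g/L.
#' @param spec A [rheo_series_spec()].
#' @return Specific viscosities.
#' @export
synthetic_eta_sp <- function(c, spec) {
  stopifnot(inherits(spec, "rheo_series_spec"))
  slopes <- spec$regime_slopes
  brk <- spec$breaks
  a_c <- spec$eta_sp_anchor[1]
  a_v <- spec$eta_sp_anchor[2]
  # anchor lies on the segment containing a_c; propagate continuity
  lx <- log(c)
  knots <- c(-Inf, log(brk), Inf)
  seg_of <- function(x) findInterval(x, log(brk)) + 1
  s0 <- seg_of(log(a_c))
  # intercept of each segment's line at log c = 0
  icpt <- numeric(length(slopes))
  icpt[s0] <- log(a_v) - slopes[s0] * log(a_c)
  if (s0 < length(slopes)) {
    for (j in (s0 + 1):length(slopes)) {
      icpt[j] <- icpt[j - 1] + (slopes[j - 1] - slopes[j]) * log(brk[j - 1])
    }
  }
  if (s0 > 1) {
    for (j in (s0 - 1):1) {
      icpt[j] <- icpt[j + 1] + (slopes[j + 1] - slopes[j]) * log(brk[j])
    }
  }
  seg <- seg_of(lx)
  exp(icpt[seg] + slopes[seg] * lx)
}

#' Ground-truth relaxation time of a synthetic series
#'
#' Constant `tau0` below the concentrated crossover, `tau0 (c/c_D)^3`
#' above it.
#'
#' @inheritParams synthetic_eta_sp
#' @return Relaxation times, s.
#' @export
synthetic_tau <- function(c, spec) {
  stopifnot(inherits(spec, "rheo_series_spec"))
  c_D <- spec$breaks[length(spec$breaks)]
  ifelse(c < c_D, spec$tau0, spec$tau0 * (c / c_D)^3)
}

#' Generate synthetic steady-shear flow curves
#'
#' Carreau curves (`eta_inf = 0`) sampled on the spec's shear-rate grid
#' with multiplicative Gaussian noise; reproducible for a fixed seed.
#'
#' @param spec A [rheo_series_spec()].
#' @return A list of [flow_curve()]s with attribute `truth`: a data frame
#'   of the generating `eta0`, `eta_sp`, `tau` and `p` per concentration.
#' @export
generate_flow_curves <- function(spec) {
  stopifnot(inherits(spec, "rheo_series_spec"))
  gdot <- spec$shear_rate_grid
  eta_sp <- synthetic_eta_sp(spec$concentrations, spec)
  eta0 <- spec$solvent_viscosity * (1 + eta_sp)
  tau <- synthetic_tau(spec$concentrations, spec)
  curves <- withr::with_seed(spec$seed, {
    lapply(seq_along(spec$concentrations), function(j) {
      eta <- eta0[j] * (1 + (tau[j] * gdot)^2)^((spec$carreau_p - 1) / 2)
      noisy <- eta * exp(stats::rnorm(length(gdot), 0, spec$noise_fraction))
      flow_curve(gdot, noisy, concentration = spec$concentrations[j])
    })
  })
  attr(curves, "truth") <- data.frame(
    concentration = spec$concentrations, eta0 = eta0, eta_sp = eta_sp,
    tau = tau, p = spec$carreau_p
  )
  curves
}
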