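make_carreau_curve <- function(eta0 = 0.5, tau = 0.05, p = 0.5,
                               noise = 0, seed = 1, concentration = 10,
                               gdot = exp(seq(log(0.01), log(800),
                                              length.out = 40))) {
  eta <- eta0 * (1 + (tau * gdot)^2)^((p - 1) / 2)
  if (noise > 0) {
    eta <- withr::with_seed(seed, eta * exp(rnorm(length(gdot), 0, noise)))
  }
  flow_curve(gdot, eta, concentration = concentration)
}

test_that("Carreau fit recovers noiseless parameters exactly", {
  cv <- make_carreau_curve(eta0 = 0.31, tau = 0.08, p = 0.45)
  fit <- carreau_fit(cv)
  expect_equal(fit$eta0, 0.31, tolerance = 1e-7)
  expect_equal(fit$tau, 0.08, tolerance = 1e-6)
  expect_equal(fit$p, 0.45, tolerance = 1e-5)
  expect_true(is.na(fit$flag))
})

test_that("Carreau fit is unbiased at 1 % noise over 30 seeds", {
  eta0s <- sapply(1:30, function(sd) {
    carreau_fit(make_carreau_curve(eta0 = 0.5, noise = 0.01, seed = sd))$eta0
  })
  expect_lt(abs(median(eta0s) / 0.5 - 1), 0.01)
})

test_that("a purely Newtonian curve yields the plateau-only flag", {
  gdot <- exp(seq(log(0.01), log(800), length.out = 30))
  cv <- flow_curve(gdot, rep(0.0021, 30), concentration = 0.5)
  fit <- carreau_fit(cv)
  expect_identical(fit$flag, "plateau_only")
  expect_equal(fit$eta0, 0.0021, tolerance = 1e-9)
  expect_true(is.na(fit$tau))
  expect_warning(relaxation_time_90(fit), "undefined")
})

test_that("zero-shear viscosity windows out high-shear inertial artefacts", {
  gdot <- exp(seq(log(0.1), log(800), length.out = 40))
  eta <- ifelse(gdot < 100, 0.002, 0.002 * (gdot / 100)^0.4)
  cv <- flow_curve(gdot, eta, concentration = 0.3)
  expect_equal(zero_shear_viscosity(cv, eta_sp_estimate = 1.2), 0.002,
               tolerance = 1e-9)
  # high-viscosity branch returns the Carreau plateau
  cv2 <- make_carreau_curve(eta0 = 0.09, tau = 0.05, p = 0.5)
  expect_equal(zero_shear_viscosity(cv2, eta_sp_estimate = 100),
               carreau_fit(cv2)$eta0)
})

test_that("plateau mean is jackknife-stable to single-point removal", {
  cv <- make_carreau_curve(eta0 = 0.002, tau = 0.004, p = 0.5,
                           noise = 0.01, seed = 4)
  full <- zero_shear_viscosity(cv, eta_sp_estimate = 1.2)
  keep <- cv$shear_rate < 100
  idx <- which(keep)
  devs <- sapply(idx, function(j) {
    cv_j <- flow_curve(cv$shear_rate[-j], cv$viscosity[-j],
                       concentration = cv$concentration)
    abs(zero_shear_viscosity(cv_j, eta_sp_estimate = 1.2) - full)
  })
  expect_lt(max(devs), 0.01 * 0.002)
})

test_that("90 % relaxation time matches the closed-form Carreau inversion", {
  for (p in c(0.3, 0.5, 0.8)) {
    fit <- carreau_fit(make_carreau_curve(eta0 = 1, tau = 0.2, p = p))
    t90 <- relaxation_time_90(fit)
    # independent numeric inversion of the fitted Carreau curve
    gd <- uniroot(function(g) {
      fit$eta0 * (1 + (fit$tau * g)^2)^((fit$p - 1) / 2) - 0.9 * fit$eta0
    }, c(1e-6, 1e6), tol = 1e-14)$root
    expect_equal(t90, 1 / gd, tolerance = 1e-8)
    expect_equal(t90, fit$tau / sqrt(0.9^(2 / (fit$p - 1)) - 1),
                 tolerance = 1e-8)
  }
  # doubling tau doubles tau_90 at fixed p
  f1 <- carreau_fit(make_carreau_curve(tau = 0.05))
  f2 <- carreau_fit(make_carreau_curve(tau = 0.10))
  expect_equal(relaxation_time_90(f2), 2 * relaxation_time_90(f1),
               tolerance = 1e-5)
})

test_that("specific viscosity is the relative viscosity increment", {
  expect_equal(specific_viscosity(0.00089, 0.00089), 0)
  expect_equal(specific_viscosity(2 * 0.00089, 0.00089), 1)
  expect_equal(specific_viscosity(0.00178, 0.00089), 1)
  expect_warning(v <- specific_viscosity(0.0005, 0.00089), "negative")
  expect_lt(v, 0)
  # invariant under joint rescaling
  expect_equal(specific_viscosity(0.004, 0.001),
               specific_viscosity(0.4, 0.1))
})

test_that("terminal modulus and per-chain energy follow their definitions", {
  expect_equal(terminal_modulus(1, 1, 10, 280000)$G, 1)
  g1 <- terminal_modulus(1, 1, 10, 280000)$per_chain_energy
  g2 <- terminal_modulus(1, 1, 5, 280000)$per_chain_energy
  expect_equal(g2, 2 * g1)
  # a modulus of kB T per chain gives exactly 1
  kB <- 1.380649e-23; NAv <- 6.02214076e23
  G <- kB * 298.15 * (1000 * 10 / 280000 * NAv)
  tm <- terminal_modulus(G, 1, 10, 280000, T = 298.15)
  expect_equal(tm$per_chain_energy, 1, tolerance = 1e-12)
})

test_that("rheo summary reproduces the generator's zero-shear viscosities", {
  spec <- rheo_series_spec(noise_fraction = 0)
  curves <- generate_flow_curves(spec)
  truth <- attr(curves, "truth")
  rs <- rheo_summary(curves, run_config())
  expect_equal(rs$concentration, truth$concentration)
  expect_equal(rs$eta0, truth$eta0, tolerance = 1e-3)
  expect_equal(rs$tau_carreau, truth$tau, tolerance = 1e-3)
  expect_true(all(rs$eta_sp > 0))
})
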