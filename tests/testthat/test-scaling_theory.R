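test_that("Bjerrum length reproduces water at 25 C and its scalings", {
  lB <- bjerrum_length(298.15, 78.4)
  expect_equal(lB, 7.1, tolerance = 0.01)
  expect_equal(bjerrum_length(298.15, 2 * 78.4), lB / 2)
  expect_equal(bjerrum_length(2 * 298.15, 78.4), lB / 2)
})

test_that("monomer molar mass matches an independent atomic-mass sum", {
  # independent sum from standard atomic weights
  am <- c(C = 12.011, H = 1.008, O = 15.999, Na = 22.98977)
  glc <- 6 * am["C"] + 10 * am["H"] + 5 * am["O"]
  sub <- 2 * am["C"] + am["H"] + 2 * am["O"] + am["Na"]  # CH2COONa minus H
  expect_equal(monomer_molar_mass(0), unname(glc), tolerance = 1e-6)
  expect_equal(monomer_molar_mass(1.2), unname(glc + 1.2 * sub),
               tolerance = 1e-6)
  expect_equal(monomer_molar_mass(1.2), 258.2, tolerance = 1e-3)
  expect_equal(monomer_molar_mass(3), 402.2, tolerance = 1e-3)
  expect_error(monomer_molar_mass(3.5), "DS")
})

test_that("Manning condensation branches and their boundary agree", {
  # condensed: spacing b/DS = 4.29 A < l_B
  expect_equal(manning_A(5.15, 1.2, 7.1), 7.1 / 5.15)
  # not condensed: spacing 10.3 A > l_B
  expect_equal(manning_A(5.15, 0.5, 7.1), 2)
  # continuity at s = l_B
  b <- 5.15
  DS <- b / 7.1
  expect_equal(manning_A(b, DS, 7.1), 1 / DS)
  expect_equal(manning_A(b, DS * (1 + 1e-9), 7.1), 7.1 / b, tolerance = 1e-8)
})

test_that("electrostatic blob formulas hit the unit case and the chain constants", {
  b <- 5.15
  lB <- bjerrum_length()
  # unit blob: A^2 b / l_B = 1
  A1 <- sqrt(lB / b)
  ub <- electrostatic_blob(A1, b, lB)
  expect_equal(ub$g_T, 1)
  expect_equal(ub$xi_T, b)
  # chain constants: condensed Manning A gives a ~6 A blob
  A <- manning_A(b, 1.2, lB)
  blob <- electrostatic_blob(A, b, lB)
  expect_equal(blob$xi_T, 6, tolerance = 0.1)
  # good-solvent branch is nearly identical for these constants
  blob_g <- electrostatic_blob(A, b, lB, "good")
  expect_equal(blob_g$xi_T, blob$xi_T, tolerance = 0.1)
  # monotone in A
  expect_gt(electrostatic_blob(2 * A, b, lB)$xi_T, blob$xi_T)
})

test_that("correlation-length prediction and B inversion match the chain constants", {
  pref <- predicted_xi(1)
  expect_equal(pref, 286, tolerance = 0.02)
  expect_equal(predicted_xi(4), pref / 2)
  expect_equal(predicted_xi(1, B = 4), 2 * pref)
  B <- B_from_prefactor(296, pref)
  expect_equal(B, 1.06, tolerance = 0.1 / 1.06)
  expect_equal(B_from_prefactor(pref, pref), 1)
  expect_equal(B_from_prefactor(2 * 296, pref), 4 * B)
  # inversion identity: predicted_xi with the recovered B reproduces 296
  expect_equal(predicted_xi(1, B = B), 296, tolerance = 1e-10)
})

test_that("peak position converts to correlation length and back", {
  expect_equal(xi_from_qstar(0.0212), 296.4, tolerance = 1e-3)
  qs <- c(0.01, 0.05, 0.2)
  expect_equal(xi_from_qstar(xi_from_qstar(qs)), qs)
  expect_equal(xi_from_qstar(0.01), 2 * xi_from_qstar(0.02))
})

test_that("scattering-based overlap solves the packing condition", {
  cstar <- overlap_from_scattering(296, 280000)
  # independent root-solve of (c NA/Mw) * (296 c^-1/2)^3 * 1e-27 = 1
  oracle <- uniroot(function(c) {
    c * 6.02214076e23 / 280000 * (296 / sqrt(c))^3 * 1e-27 - 1
  }, c(1e-6, 1), tol = 1e-14)$root
  expect_equal(cstar, oracle, tolerance = 1e-8)
  expect_equal(cstar, 3.1e-3, tolerance = 0.02)
  # residual of the defining equation
  resid <- cstar * 6.02214076e23 / 280000 * (296 / sqrt(cstar))^3 * 1e-27 - 1
  expect_lt(abs(resid), 1e-10)
  # c* scales as M_w^-2: heavier chains need a larger mesh to overlap
  expect_equal(overlap_from_scattering(296, 2 * 280000), cstar / 4)
})

test_that("entanglement overlap number brackets the printed bounds", {
  expect_equal(entanglement_n(2.9, 0.07), 2.6, tolerance = 0.15 / 2.6)
  expect_equal(entanglement_n(2.9, overlap_from_scattering(296, 280000)),
               5.5, tolerance = 0.05)
  expect_equal(entanglement_n(3.1, 3.1), 1)
  expect_error(entanglement_n(0.05, 0.07), "c_e")
})

test_that("tube diameter is the blob-count multiple of the correlation length", {
  expect_equal(tube_diameter(123, 1), 123)
  expect_equal(tube_diameter(80, 3.2), 256)
  expect_equal(tube_diameter(2 * 80, 3.2), 2 * tube_diameter(80, 3.2))
})

test_that("viscosity scaling predictions have the right exponents and B-dependence", {
  params <- list(b = 5.15, M0 = monomer_molar_mass(1.2),
                 N = 280000 / monomer_molar_mass(1.2), B = 1)
  cs <- exp(seq(log(0.1), log(2), length.out = 10))
  expect_equal(loglog_slope(cs, predicted_eta_sp(cs, "unentangled", params)),
               0.5, tolerance = 1e-10)
  # ratio between B = 1 and B = 2.3 predictions
  p23 <- modifyList(params, list(B = 2.3))
  ratio <- predicted_eta_sp(1, "unentangled", params) /
    predicted_eta_sp(1, "unentangled", p23)
  expect_equal(ratio, 2.3^1.5, tolerance = 1e-12)
  expect_equal(ratio, 3.5, tolerance = 0.01)
  # entangled branch: c^(3/2) and continuity at c_e when prefactors match
  ce <- 4
  cs_e <- exp(seq(log(4), log(14), length.out = 8))
  expect_equal(loglog_slope(cs_e, predicted_eta_sp(cs_e, "entangled", params,
                                                   n_entanglement = 3.2)),
               1.5, tolerance = 1e-10)
  # matching construction: choose n so that the two branches meet at c_e
  c_n <- ce * 6.02214076e23 / params$M0 / 1e27
  g <- c_n * sqrt(1 / (params$b * c_n))^3
  n_star <- sqrt(params$N / g)
  expect_equal(predicted_eta_sp(ce, "entangled", params, n_entanglement = n_star),
               predicted_eta_sp(ce, "unentangled", params), tolerance = 1e-10)
  # concentrated branch continues from c_D with slope 15/4
  cs_c <- exp(seq(log(14.3), log(40), length.out = 6))
  v <- predicted_eta_sp(cs_c, "concentrated", params, n_entanglement = 3.2,
                        c_D = 14.3)
  expect_equal(loglog_slope(cs_c, v), 3.75, tolerance = 1e-10)
  expect_equal(v[1], predicted_eta_sp(14.3, "entangled", params,
                                      n_entanglement = 3.2), tolerance = 1e-10)
})

test_that("scaling report assembles the derived-quantity chain", {
  rep <- scaling_report(run_config(), xi_prefactor = 296, c_e = 2.9,
                        c_D = 14.4, c_star_viscosity = 0.07)
  expect_equal(rep$B, B_from_prefactor(296, predicted_xi(1)))
  expect_equal(rep$n_from_viscosity, entanglement_n(2.9, 0.07))
  expect_equal(rep$xi_at_cD, 296 / sqrt(14.4))
  expect_equal(rep$xi_at_cD, 80, tolerance = 0.05)
  expect_equal(rep$tube_diameter_at_cD, rep$n_from_scattering * rep$xi_at_cD)
})
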