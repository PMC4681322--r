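#' Bjerrum length
#'
#' Distance at which the Coulomb energy of two unit charges equals the
#' thermal energy: `l_B = e^2 / (4 pi eps0 epsilon_r kB T)`. About 7.1
#' Angstrom for water at 25 C.
#'
#' @param T Absolute temperature, K.
#' @param epsilon_r Relative permittivity of the solvent (78.4 for light
#'   water at 25 C).
#' @return Bjerrum length, Angstrom.
#' @export
bjerrum_length <- function(T = 298.15, epsilon_r = 78.4) {
  if (any(T <= 0) || any(epsilon_r <= 0)) stop("T and epsilon_r must be positive")
  lB_m <- .const$e^2 / (4 * pi * .const$eps0 * epsilon_r * .const$kB * T)
  lB_m / .const$m_per_A
}

#' Monomer molar mass of carboxymethyl cellulose
#'
#' Anhydroglucose (C6H10O5) plus, per degree of substitution, one
#' carboxymethyl sodium group replacing a hydroxyl hydrogen
#' (net +CH2COONa -H).
#'
#' @param DS Degree of substitution, average carboxymethyl groups per
#'   monomer, in `[0, 3]`.
#' @return Monomer molar mass, g/mol.
#' @export
monomer_molar_mass <- function(DS) {
  if (any(DS < 0) || any(DS > 3)) stop("DS must be in [0, 3]")
  am <- .atomic_mass
  anhydroglucose <- 6 * am["C"] + 10 * am["H"] + 5 * am["O"]
  substituent <- 2 * am["C"] + 2 * am["H"] + 2 * am["O"] + am["Na"] - am["H"]
  unname(anhydroglucose + DS * substituent)
}

#' Monomers per effective charge after Manning condensation
#'
#' The bare charge spacing along the chain is `s = b / DS`. If `s >= l_B`
#' no counterions condense and the effective charge fraction is the bare one
#' (`A = 1/DS` monomers per charge); otherwise condensation caps the charge
#' spacing at the Bjerrum length, giving `A = l_B / b`. The two branches
#' agree at `s = l_B`.
#'
#' @param b Monomer length, Angstrom.
#' @param DS Degree of substitution (bare charges per monomer).
#' @param l_B Bjerrum length, Angstrom.
#' @return `A`, monomers per effective charge (dimensionless, `>= 1/DS`).
#' @export
manning_A <- function(b, DS, l_B) {
  if (b <= 0 || DS <= 0 || l_B <= 0) stop("inputs must be positive")
  s <- b / DS
  if (s >= l_B) 1 / DS else l_B / b
}

#' Electrostatic blob size and monomers per blob
#'
#' Within an electrostatic blob, thermal energy dominates the Coulomb
#' repulsion and the chain keeps its bare (solvent-quality-dependent)
#' statistics; beyond it the chain is stretched. For the theta/poor-solvent
#' branch (the default; appropriate here because the backbone is
#' hydrophobic) `g_T = (A^2 b / l_B)^(2/3)` and `xi_T = b g_T^(1/2)`. The
#' good-solvent branch (`g_T = u^(6/7)`, `xi_T = b g_T^(3/5)`, with
#' `u = A^2 b / l_B`) gives nearly identical values for these chain
#' constants.
#'
#' @param A Monomers per effective charge (see [manning_A()]).
#' @param b Monomer length, Angstrom.
#' @param l_B Bjerrum length, Angstrom.
#' @param solvent_quality `"theta"` (default) or `"good"`.
#' @return A list with `xi_T` (blob size, Angstrom) and `g_T` (monomers per
#'   blob).
#' @export
electrostatic_blob <- function(A, b, l_B, solvent_quality = c("theta", "good")) {
  if (A <= 0 || b <= 0 || l_B <= 0) stop("inputs must be positive")
  solvent_quality <- match.arg(solvent_quality)
  u <- A^2 * b / l_B
  if (solvent_quality == "theta") {
    g_T <- u^(2 / 3)
    xi_T <- b * sqrt(g_T)
  } else {
    g_T <- u^(6 / 7)
    xi_T <- b * g_T^(3 / 5)
  }
  list(xi_T = xi_T, g_T = g_T)
}

#' Scaling prediction for the correlation length
#'
#' In the semidilute regime the correlation blob contains a locally
#' stretched strand, giving `xi = (B / (b c_n))^(1/2)` with `c_n` the
#' monomer number density. With `B = 1` (chain rigid up to `xi`) and the
#' chain constants of carboxymethyl cellulose this evaluates to about
#' 286 Angstrom at c = 1 g/L.
#'
#' @param c Polymer concentration, g/L.
#' @param B Stretching parameter (contour length over dilute end-to-end
#'   length; 1 for a locally rod-like chain).
#' @param b Monomer length, Angstrom.
#' @param M0 Monomer molar mass, g/mol.
#' @return Correlation length, Angstrom.
#' @export
predicted_xi <- function(c, B = 1, b = 5.15, M0 = monomer_molar_mass(1.2)) {
  if (any(c <= 0) || B <= 0 || b <= 0 || M0 <= 0) {
    stop("inputs must be positive")
  }
  c_n <- c * .const$NA_ / M0 / .const$A3_per_L # monomers per cubic Angstrom
  sqrt(B / (b * c_n))
}

#' Stretching parameter from measured and predicted correlation-length
#' prefactors
#'
#' Since `xi` scales as `B^(1/2)`, the stretching parameter follows from
#' the measured `xi = P c^(-1/2)` prefactor and the `B = 1` prediction as
#' `B = (measured / predicted)^2`.
#'
#' @param measured_prefactor Measured prefactor, Angstrom (g/L)^(1/2).
#' @param predicted_prefactor_at_B1 Predicted prefactor at `B = 1`, same
#'   units (e.g. `predicted_xi(1)`).
#' @return `B`, dimensionless.
#' @export
B_from_prefactor <- function(measured_prefactor, predicted_prefactor_at_B1) {
  if (measured_prefactor <= 0 || predicted_prefactor_at_B1 <= 0) {
    stop("inputs must be positive")
  }
  (measured_prefactor / predicted_prefactor_at_B1)^2
}

#' Correlation length from the scattering peak position
#'
#' `xi = 2 pi / q*`; self-inverse, so it also converts a correlation-length
#' prefactor into a `q*` prefactor and back.
#'
#' @param q_star Peak position, 1/Angstrom (or a `q*` prefactor).
#' @return Correlation length, Angstrom (or a `xi` prefactor).
#' @export
xi_from_qstar <- function(q_star) {
  if (any(q_star <= 0)) stop("q_star must be positive")
  2 * pi / q_star
}

#' Overlap concentration from the measured correlation length
#'
#' At overlap, chains with end-to-end distance equal to the semidilute
#' correlation length extrapolated to `c*` just fill the solution:
#' `(c N_A / M_w) xi(c)^3 = 1` with `xi(c) = prefactor c^(-1/2)`. In
#' consistent volume units the closed form is
#' `c* = (N_A prefactor^3 / (M_w * 1e27))^2` for `c*` in g/L and the
#' prefactor in Angstrom (g/L)^(1/2).
#'
#' @param xi_prefactor Measured correlation-length prefactor,
#'   Angstrom (g/L)^(1/2).
#' @param M_w Weight-average molar mass, g/mol.
#' @return Overlap concentration, g/L.
#' @export
overlap_from_scattering <- function(xi_prefactor, M_w) {
  if (xi_prefactor <= 0 || M_w <= 0) stop("inputs must be positive")
  (.const$NA_ * xi_prefactor^3 / (M_w * .const$A3_per_L))^2
}

#' Chain overlaps per entanglement
#'
#' From the crossover relation `c_e = n^4 c*`:
#' `n = (c_e / c*)^(1/4)`.
#'
#' @param c_e Entanglement concentration, g/L.
#' @param c_star Overlap concentration, g/L.
#' @return `n`, dimensionless.
#' @export
entanglement_n <- function(c_e, c_star) {
  if (c_star <= 0) stop("c_star must be positive")
  if (c_e < c_star) stop("c_e must be >= c_star")
  (c_e / c_star)^(1 / 4)
}

#' Tube diameter from the correlation length
#'
#' The entanglement strand spans `n` correlation blobs: `a = n xi`.
#'
#' @param xi_at_c Correlation length at the concentration of interest,
#'   Angstrom.
#' @param n Chain overlaps per entanglement.
#' @return Tube diameter, Angstrom.
#' @export
tube_diameter <- function(xi_at_c, n) {
  if (xi_at_c <= 0 || n <= 0) stop("inputs must be positive")
  n * xi_at_c
}

#' Scaling predictions for the specific viscosity
#'
#' Order-of-magnitude scaling forms (prefactors of order unity are set to
#' 1):
#' * unentangled (Fuoss law): `eta_sp = N (c_n b^3)^(1/2) B^(-3/2)`,
#'   a `c^(1/2)` power law;
#' * entangled: the unentangled form times the squared number of
#'   entanglements per chain `((N/g)/n^2)^2` with `g = c_n xi^3` monomers
#'   per correlation blob, giving a `c^(3/2)` power law and an `n^(-4)`
#'   dependence on the overlaps-per-entanglement number;
#' * concentrated: neutral-polymer-like `c^(15/4)` continued from the
#'   entangled prediction at `c_D`.
#'
#' The absolute normalisation is order-of-magnitude only; ratios (e.g.
#' between two `B` values) are meaningful.
#'
#' @param c Concentration, g/L.
#' @param regime One of `"unentangled"`, `"entangled"`, `"concentrated"`.
#' @param params A list with chain constants `b` (Angstrom), `M0` (g/mol),
#'   `N` (degree of polymerization) and `B` (stretching parameter).
#' @param n_entanglement Chain overlaps per entanglement (required for the
#'   entangled and concentrated regimes).
#' @param c_D Crossover to the concentrated regime, g/L (required for the
#'   concentrated regime).
#' @return Predicted specific viscosity, dimensionless.
#' @export
predicted_eta_sp <- function(c, regime = c("unentangled", "entangled",
                                           "concentrated"),
                             params, n_entanglement = NULL, c_D = NULL) {
  regime <- match.arg(regime)
  b <- params$b
  M0 <- params$M0
  N <- params$N
  B <- if (is.null(params$B)) 1 else params$B
  if (any(c <= 0) || b <= 0 || M0 <= 0 || N <= 0 || B <= 0) {
    stop("inputs must be positive")
  }
  c_n <- c * .const$NA_ / M0 / .const$A3_per_L
  rouse <- N * sqrt(c_n * b^3) * B^(-3 / 2)
  if (regime == "unentangled") return(rouse)
  if (is.null(n_entanglement)) {
    stop("n_entanglement is required for the entangled/concentrated regimes")
  }
  xi <- sqrt(B / (b * c_n))
  g <- c_n * xi^3
  ent <- rouse * ((N / g) / n_entanglement^2)^2
  if (regime == "entangled") return(ent)
  if (is.null(c_D)) stop("c_D is required for the concentrated regime")
  c_nD <- c_D * .const$NA_ / M0 / .const$A3_per_L
  xiD <- sqrt(B / (b * c_nD))
  gD <- c_nD * xiD^3
  entD <- N * sqrt(c_nD * b^3) * B^(-3 / 2) * ((N / gD) / n_entanglement^2)^2
  entD * (c / c_D)^(15 / 4)
}

#' Derived scaling quantities linking scattering and rheology
#'
#' Computes, from a run configuration and the measured correlation-length
#' prefactor and rheological crossovers, the chain constants and derived
#' quantities of the scaling analysis: Bjerrum length, Manning `A`,
#' electrostatic blob (`xi_T`, `g_T`), the `B = 1` correlation-length
#' prefactor and the stretching parameter `B`, scattering- and
#' viscosity-based overlap concentrations, the corresponding bounds on the
#' entanglement overlap number `n`, the correlation length at `c_D` and the
#' tube diameter there.
#'
#' @param config A [run_config()].
#' @param xi_prefactor Measured correlation-length prefactor,
#'   Angstrom (g/L)^(1/2).
#' @param c_e Entanglement crossover concentration, g/L.
#' @param c_D Concentrated crossover concentration, g/L.
#' @param c_star_viscosity Viscosity-extrapolated overlap concentration,
#'   g/L (optional; enables the viscosity-based `n` bound).
#' @param solvent_quality Blob branch, `"theta"` (default) or `"good"`.
#' @return A named list of derived quantities (lengths in Angstrom,
#'   concentrations in g/L).
#' @export
scaling_report <- function(config, xi_prefactor, c_e, c_D,
                           c_star_viscosity = NULL,
                           solvent_quality = "theta") {
  stopifnot(inherits(config, "run_config"))
  b <- config$monomer_length_b
  DS <- config$degree_of_substitution
  M0 <- monomer_molar_mass(DS)
  M_w <- config$weight_avg_molar_mass
  l_B <- bjerrum_length(config$temperature, config$relative_permittivity)
  A <- manning_A(b, DS, l_B)
  blob <- electrostatic_blob(A, b, l_B, solvent_quality)
  pred <- predicted_xi(1, B = 1, b = b, M0 = M0)
  B <- B_from_prefactor(xi_prefactor, pred)
  c_star_scatt <- overlap_from_scattering(xi_prefactor, M_w)
  n_upper <- entanglement_n(c_e, c_star_scatt)
  n_lower <- if (!is.null(c_star_viscosity)) {
    entanglement_n(c_e, c_star_viscosity)
  } else {
    NA_real_
  }
  xi_cD <- xi_prefactor / sqrt(c_D)
  list(
    l_B = l_B, A = A, xi_T = blob$xi_T, g_T = blob$g_T,
    M0 = M0, N = M_w / M0,
    predicted_xi_prefactor_B1 = pred, B = B,
    c_star_scattering = c_star_scatt,
    c_star_viscosity = if (is.null(c_star_viscosity)) NA_real_ else c_star_viscosity,
    n_from_scattering = n_upper, n_from_viscosity = n_lower,
    xi_at_cD = xi_cD,
    tube_diameter_at_cD = tube_diameter(xi_cD, n_upper)
  )
}
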