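#' Construct a SANS profile
#'
#' A `sans_profile` holds one reduced 1-D small-angle neutron scattering
#' curve in absolute units together with its sample metadata. The momentum
#' transfer axis is stored strictly increasing; rows are reordered if needed.
#'
#' @param q Momentum transfer, 1/Angstrom. Strictly positive.
#' @param intensity Absolute (coherent + incoherent) intensity, 1/cm.
#' @param d_intensity 1-sigma uncertainty on `intensity`, 1/cm. Strictly
#'   positive.
#' @param concentration Polymer mass concentration, g/L.
#' @param temperature Sample temperature, degrees C.
#' @param instrument_label Free-text instrument tag.
#' @return An object of class `sans_profile`: a list with elements `q`,
#'   `intensity`, `d_intensity`, `concentration`, `temperature`,
#'   `instrument_label`.
#' @export
sans_profile <- function(q, intensity, d_intensity, concentration,
                         temperature = 25, instrument_label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  d_intensity <- as.numeric(d_intensity)
  n <- length(q)
  if (length(intensity) != n || length(d_intensity) != n) {
    stop("q, intensity and d_intensity must have equal length")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("q must be finite and strictly positive")
  }
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (any(!is.finite(d_intensity)) || any(d_intensity <= 0)) {
    stop("d_intensity must be finite and strictly positive")
  }
  ord <- order(q)
  q <- q[ord]
  if (any(diff(q) == 0)) stop("q values must be distinct")
  structure(
    list(
      q = q, intensity = intensity[ord], d_intensity = d_intensity[ord],
      concentration = as.numeric(concentration),
      temperature = as.numeric(temperature),
      instrument_label = as.character(instrument_label)
    ),
    class = "sans_profile"
  )
}

#' @export
print.sans_profile <- function(x, ...) {
  cat(sprintf(
    "<sans_profile> %d points, q in [%.4g, %.4g] 1/A, c = %.3g g/L, T = %g C%s\n",
    length(x$q), min(x$q), max(x$q), x$concentration, x$temperature,
    if (nzchar(x$instrument_label)) paste0(" [", x$instrument_label, "]") else ""
  ))
  invisible(x)
}

#' @export
length.sans_profile <- function(x) length(x$q)

#' Construct a steady-shear flow curve
#'
#' @param shear_rate Shear rate, 1/s. Strictly positive; stored increasing.
#' @param viscosity Dynamic viscosity, Pa s. Strictly positive.
#' @param concentration Polymer mass concentration, g/L.
#' @param temperature Sample temperature, degrees C.
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(shear_rate, viscosity, concentration,
                       temperature = 25) {
  shear_rate <- as.numeric(shear_rate)
  viscosity <- as.numeric(viscosity)
  if (length(shear_rate) != length(viscosity)) {
    stop("shear_rate and viscosity must have equal length")
  }
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0)) {
    stop("shear_rate must be finite and strictly positive")
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    stop("viscosity must be finite and strictly positive")
  }
  ord <- order(shear_rate)
  shear_rate <- shear_rate[ord]
  if (any(diff(shear_rate) == 0)) stop("shear_rate values must be distinct")
  structure(
    list(
      shear_rate = shear_rate, viscosity = viscosity[ord],
      concentration = as.numeric(concentration),
      temperature = as.numeric(temperature)
    ),
    class = "flow_curve"
  )
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf(
    "<flow_curve> %d points, shear rate in [%.3g, %.3g] 1/s, c = %.3g g/L\n",
    length(x$shear_rate), min(x$shear_rate), max(x$shear_rate),
    x$concentration
  ))
  invisible(x)
}

#' @export
length.flow_curve <- function(x) length(x$shear_rate)

#' Read a reduced SANS profile from a 3-column ASCII file
#'
#' Accepts the common reduced-data exports of SANS facilities: whitespace- or
#' comma-delimited columns `q I dI` with `#` comment lines. Rows with
#' non-finite values, non-positive `q`, or non-positive `dI` are dropped with
#' a warning naming the offending rows.
#'
#' @param path Path to the file.
#' @param concentration Polymer concentration of the sample, g/L.
#' @param temperature Sample temperature, degrees C.
#' @param instrument_label Instrument tag; defaults to the file name.
#' @return A [sans_profile()], sorted by `q`.
#' @export
read_sans_profile <- function(path, concentration, temperature = 25,
                              instrument_label = basename(path)) {
  tab <- .read_numeric_table(path, min_cols = 3)
  q <- tab[, 1]
  i <- tab[, 2]
  di <- tab[, 3]
  ok <- is.finite(q) & is.finite(i) & is.finite(di) & q > 0 & di > 0
  if (any(!ok)) {
    warning(sprintf(
      "%s: dropped %d invalid row(s) (non-finite, q <= 0, or dI <= 0): %s",
      basename(path), sum(!ok),
      paste(utils::head(which(!ok), 10), collapse = ", ")
    ))
  }
  if (sum(ok) < 10) {
    stop(sprintf("%s: fewer than 10 valid rows (%d)", path, sum(ok)))
  }
  sans_profile(q[ok], i[ok], di[ok], concentration, temperature,
               instrument_label)
}

#' Write a SANS profile as 3-column ASCII
#'
#' Writes `q I dI` columns at 9 significant digits with `#` metadata header
#' lines; [read_sans_profile()] is its exact inverse.
#'
#' @param profile A [sans_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sans_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sans_profile"))
  hdr <- c(
    sprintf("# concentration_g_per_L %.9g", profile$concentration),
    sprintf("# temperature_C %.9g", profile$temperature),
    sprintf("# instrument %s", profile$instrument_label),
    "# q_invA I_invcm dI_invcm"
  )
  rows <- sprintf("%.9g %.9g %.9g", profile$q, profile$intensity,
                  profile$d_intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a steady-shear flow curve from CSV
#'
#' Expects a header naming a shear-rate column (matched on "shear") and a
#' viscosity column (matched on "visc"). Rows with non-finite or non-positive
#' values are dropped with a warning naming the offending rows.
#'
#' @inheritParams read_sans_profile
#' @return A [flow_curve()], sorted by shear rate.
#' @export
read_flow_curve <- function(path, concentration, temperature = 25) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  nm <- tolower(names(tab))
  i_sr <- which(grepl("shear", nm))[1]
  i_vi <- which(grepl("visc", nm))[1]
  if (is.na(i_sr) || is.na(i_vi)) {
    stop(sprintf("%s: header must name shear-rate and viscosity columns", path))
  }
  sr <- as.numeric(tab[[i_sr]])
  vi <- as.numeric(tab[[i_vi]])
  ok <- is.finite(sr) & is.finite(vi) & sr > 0 & vi > 0
  if (any(!ok)) {
    warning(sprintf(
      "%s: dropped %d invalid row(s) (non-finite or non-positive): %s",
      basename(path), sum(!ok),
      paste(utils::head(which(!ok), 10), collapse = ", ")
    ))
  }
  if (sum(ok) < 2) stop(sprintf("%s: fewer than 2 valid rows", path))
  flow_curve(sr[ok], vi[ok], concentration, temperature)
}

#' Write a flow curve as CSV
#'
#' @param curve A [flow_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_curve <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  lines <- c(
    sprintf("# concentration_g_per_L %.9g", curve$concentration),
    "shear_rate_s-1,viscosity_Pa_s",
    sprintf("%.9g,%.9g", curve$shear_rate, curve$viscosity)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Correct a nominal concentration for residual water content
#'
#' Freeze-dried polysaccharides retain water; a nominal concentration made up
#' by mass therefore overstates the polymer content. The corrected
#' concentration is `nominal_c * (1 - water_mass_fraction)`.
#'
#' @param nominal_c Nominal concentration, g/L.
#' @param water_mass_fraction Mass fraction of water in the dry polymer,
#'   in `[0, 1)`.
#' @return Corrected concentration, g/L.
#' @export
correct_concentration <- function(nominal_c, water_mass_fraction) {
  if (any(water_mass_fraction < 0) || any(water_mass_fraction >= 1)) {
    stop("water_mass_fraction must be in [0, 1)")
  }
  nominal_c * (1 - water_mass_fraction)
}

#' Run configuration for the analysis pipeline
#'
#' Central container for the chemical and numerical constants of a run. All
#' units are fixed by contract: viscosities in Pa s, lengths in Angstrom,
#' temperature in K, molar masses in g/mol.
#'
#' @param solvent_viscosity Solvent dynamic viscosity, Pa s (default light
#'   water at 25 C).
#' @param relative_permittivity Solvent relative permittivity (default 78.4,
#'   light water at 25 C).
#' @param temperature Absolute temperature, K.
#' @param monomer_length_b Monomer (backbone repeat) length, Angstrom.
#' @param degree_of_substitution Average carboxymethyl groups per monomer,
#'   in `[0, 3]`.
#' @param weight_avg_molar_mass Weight-average molar mass, g/mol.
#' @param water_mass_fraction Residual water mass fraction of the dry
#'   polymer, in `[0, 1)`.
#' @param upturn_exponent Low-q upturn power-law exponent (fixed during
#'   fitting).
#' @param fit_window_factor High-q fit window starts at
#'   `fit_window_factor * q*`.
#' @param random_seed Integer seed for any stochastic step.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(solvent_viscosity = 8.9e-4,
                       relative_permittivity = 78.4,
                       temperature = 298.15,
                       monomer_length_b = 5.15,
                       degree_of_substitution = 1.2,
                       weight_avg_molar_mass = 280000,
                       water_mass_fraction = 0.18,
                       upturn_exponent = 3.6,
                       fit_window_factor = 1.5,
                       random_seed = 1L) {
  cfg <- list(
    solvent_viscosity = as.numeric(solvent_viscosity),
    relative_permittivity = as.numeric(relative_permittivity),
    temperature = as.numeric(temperature),
    monomer_length_b = as.numeric(monomer_length_b),
    degree_of_substitution = as.numeric(degree_of_substitution),
    weight_avg_molar_mass = as.numeric(weight_avg_molar_mass),
    water_mass_fraction = as.numeric(water_mass_fraction),
    upturn_exponent = as.numeric(upturn_exponent),
    fit_window_factor = as.numeric(fit_window_factor),
    random_seed = as.integer(random_seed)
  )
  pos <- c("solvent_viscosity", "relative_permittivity", "temperature",
           "monomer_length_b", "weight_avg_molar_mass", "upturn_exponent",
           "fit_window_factor")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("%s must be positive and finite", f))
    }
  }
  if (cfg$degree_of_substitution < 0 || cfg$degree_of_substitution > 3) {
    stop("degree_of_substitution must be in [0, 3]")
  }
  if (cfg$water_mass_fraction < 0 || cfg$water_mass_fraction >= 1) {
    stop("water_mass_fraction must be in [0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Read or write a run configuration as a flat YAML key-value file
#'
#' @param path File path.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @param config A [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a named list of results as JSON
#'
#' Machine-readable results file used by the pipeline drivers; scalars are
#' written as bare JSON numbers at full precision.
#'
#' @param results A named list of scalars or flat lists.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Read a '#'-commented numeric table, auto-detecting comma vs whitespace
# delimiters. Returns a numeric matrix with >= min_cols columns.
.read_numeric_table <- function(path, min_cols = 3) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop(sprintf("%s: no data rows", path))
  sep <- if (grepl(",", lines[[1]])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           fill = TRUE, stringsAsFactors = FALSE)
  # tolerate a header row of column names
  if (!all(vapply(tab[1, ], function(v) is.numeric(v) ||
                    !is.na(suppressWarnings(as.numeric(v))), logical(1)))) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (ncol(tab) < min_cols) {
    stop(sprintf("%s: expected at least %d numeric columns, found %d",
                 path, min_cols, ncol(tab)))
  }
  m <- suppressWarnings(apply(as.matrix(tab[, seq_len(max(min_cols, ncol(tab)))]),
                              2, as.numeric))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}
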