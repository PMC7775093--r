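#' Discrete x-ray beam model
#'
#' An imaging beam is represented by a discrete energy spectrum: a strictly
#' increasing energy grid (keV) with non-negative fluence weights, normalized
#' to sum to one.  A length-1 grid is a monoenergetic beam.
#'
#' @param energy Energy grid, keV, strictly increasing.
#' @param weight Fluence weights, same length, non-negative, not all zero.
#' @param label Beam label, e.g. `"kV120"` or `"MV3.5"`.
#' @return A `humol_beam` object with elements `energy`, `weight`, `label`
#'   and `mean_energy` (fluence-weighted, keV).
#' @export
beam_model <- function(energy, weight, label = "beam") {
  if (length(energy) < 1 || length(energy) != length(weight)) {
    stop("energy and weight must be equal-length, non-empty", call. = FALSE)
  }
  if (length(energy) > 1 && any(diff(energy) <= 0)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  if (any(weight < 0) || sum(weight) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  weight <- weight / sum(weight)
  structure(list(energy = energy, weight = weight, label = label,
                 mean_energy = sum(energy * weight)),
            class = "humol_beam")
}

#' @export
print.humol_beam <- function(x, ...) {
  cat(sprintf("<beam %s> %d energies, %.1f-%.1f keV, mean %.1f keV\n",
              x$label, length(x$energy), min(x$energy), max(x$energy),
              x$mean_energy))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' @param path CSV with columns `energy_kev`, `weight` (header required;
#'   `#` comment lines allowed).
#' @param label Beam label.
#' @return A [beam_model()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_kev", "weight") %in% names(df))) {
    stop("spectrum file needs columns energy_kev, weight", call. = FALSE)
  }
  beam_model(df$energy_kev, df$weight, label = label)
}

#' Elemental mass-attenuation table
#'
#' Loads a long-format CSV (`element`, `energy_kev`, `mu_over_rho`) into a
#' per-element lookup with log-log linear interpolation, the standard practice
#' for XCOM-style grids.  Absorption edges are assumed grid-resolved; the
#' biologically relevant elements have none in the imaging range.
#'
#' @param path CSV path; defaults to the bundled XCOM-style compilation.
#' @return A `humol_attenuation` object (named list of energy/mu tables).
#' @export
attenuation_table <- function(path = system.file("extdata",
                                                 "mass_attenuation_xcomstyle.csv",
                                                 package = "humol")) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("element", "energy_kev", "mu_over_rho") %in% names(df)))
  tabs <- lapply(split(df, df$element), function(d) {
    d <- d[order(d$energy_kev), ]
    if (any(diff(d$energy_kev) <= 0)) stop("energy grid not strictly increasing")
    if (any(d$mu_over_rho <= 0)) stop("mu/rho must be positive")
    list(energy = d$energy_kev, mu = d$mu_over_rho)
  })
  structure(tabs, class = "humol_attenuation")
}

# log-log interpolation of one element's mu/rho; errors outside the grid
element_mu_over_rho <- function(table, element, energy) {
  el <- table[[element]]
  if (is.null(el)) {
    stop("no attenuation data for element: ", element, call. = FALSE)
  }
  if (any(energy < min(el$energy)) || any(energy > max(el$energy))) {
    stop(sprintf("energy outside attenuation grid (%g-%g keV) for %s",
                 min(el$energy), max(el$energy), element), call. = FALSE)
  }
  exp(stats::approx(log(el$energy), log(el$mu), xout = log(energy))$y)
}

#' Mass attenuation coefficient of a mixture
#'
#' The mixture rule: `mu/rho` of a compound or mixture is the mass-fraction
#' weighted sum of its elemental `mu/rho` values at the same energy.
#'
#' @param elem An [elemental_composition()] (or coercible named vector).
#' @param table A [attenuation_table()].
#' @param energy Photon energy(ies), keV, inside every element's grid.
#' @return `mu/rho` in cm^2/g, same length as `energy`.
#' @export
#' @examples
#' tab <- attenuation_table()
#' mixture_mu_over_rho(c(H = 0.1119, O = 0.8881), tab, 60)
mixture_mu_over_rho <- function(elem, table, energy) {
  if (!inherits(elem, "elemental_composition")) {
    elem <- elemental_composition(elem)
  }
  stopifnot(inherits(table, "humol_attenuation"))
  out <- numeric(length(energy))
  for (sym in names(elem)) {
    out <- out + unclass(elem)[[sym]] * element_mu_over_rho(table, sym, energy)
  }
  out
}

#' Spectrum-weighted mass attenuation coefficient
#'
#' Fluence-weighted average of [mixture_mu_over_rho()] over a beam's energy
#' grid.  A monoenergetic beam reduces exactly to pointwise evaluation.
#'
#' @inheritParams mixture_mu_over_rho
#' @param beam A [beam_model()].
#' @return Scalar `mu/rho` in cm^2/g.
#' @export
spectrum_weighted_mu_over_rho <- function(elem, beam, table) {
  stopifnot(inherits(beam, "humol_beam"))
  sum(beam$weight * mixture_mu_over_rho(elem, table, beam$energy))
}

#' Gamma-PDF megavoltage beam spectrum
#'
#' MVCT spectra are modeled with a gamma probability density sampled on a
#' discrete grid and renormalized.  The default configuration (shape 1.5,
#' grid 100-3000 keV, scale solved so the grid-weighted mean energy is
#' 860 keV) puts the spectral mode near 0.3 MeV with a long high-energy tail,
#' the qualitative shape of published 3.5 MV fan-beam spectra; the grid floor
#' reflects target/filter self-absorption of the lowest energies.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param scale Gamma scale, keV (> 0), or `NULL` to solve for the scale that
#'   achieves `mean_energy` on the (truncated) grid.
#' @param grid Energy grid, keV.
#' @param mean_energy Target fluence-weighted mean (keV) used when
#'   `scale = NULL`.
#' @param label Beam label.
#' @return A [beam_model()]; its `mean_energy` element reports the achieved
#'   weighted mean.
#' @export
#' @examples
#' mv <- gamma_spectrum()
#' mv$mean_energy  # 860
gamma_spectrum <- function(shape = 1.5, scale = NULL,
                           grid = seq(100, 3000, by = 10),
                           mean_energy = 860, label = "MV3.5") {
  if (shape <= 0) stop("shape must be positive", call. = FALSE)
  if (is.null(scale)) {
    f <- function(sc) {
      w <- stats::dgamma(grid, shape = shape, scale = sc)
      sum(w * grid) / sum(w) - mean_energy
    }
    scale <- stats::uniroot(f, c(1, 10 * mean_energy))$root
  }
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  w <- stats::dgamma(grid, shape = shape, scale = scale)
  beam_model(grid, w, label = label)
}

#' Filtered Kramers kilovoltage spectrum
#'
#' A 120 kVp-like tube spectrum: Kramers bremsstrahlung fluence
#' `(kvp - E)/E` hardened by a copper filter attenuated with the bundled Cu
#' `mu/rho` curve.  This is the generator of the bundled example kV spectrum;
#' measured or externally computed spectra can be supplied instead via
#' [read_spectrum()].
#'
#' @param kvp Tube potential, kV.
#' @param filtration_mm_cu Copper filtration thickness, mm.
#' @param grid Energy grid, keV (defaults to 20..kvp in 1 keV steps).
#' @param table Attenuation table supplying the Cu curve.
#' @param label Beam label.
#' @return A [beam_model()].
#' @export
filtered_kramers_spectrum <- function(kvp = 120, filtration_mm_cu = 1.25,
                                      grid = seq(20, kvp, by = 1),
                                      table = attenuation_table(),
                                      label = sprintf("kV%d", kvp)) {
  if (kvp <= 0 || filtration_mm_cu < 0) {
    stop("kvp must be positive and filtration non-negative", call. = FALSE)
  }
  grid <- grid[grid < kvp]
  rho_cu <- 8.96  # g/cc
  mu_cu <- element_mu_over_rho(table, "Cu", grid)
  w <- (kvp - grid) / grid * exp(-mu_cu * rho_cu * filtration_mm_cu / 10)
  beam_model(grid, w, label = label)
}

#' Spectrum-route alpha coefficients
#'
#' The alphas of the molecular HU_rho relation are, by definition,
#' `alpha_i = 1000 * ((mu/rho)_i / (mu/rho)_water - 1)` with each mass
#' attenuation coefficient weighted over the beam spectrum.  This is the
#' "known spectrum" calibration route; [fit_alpha_from_phantom()] is the
#' phantom-scan alternative.
#'
#' @param molecules Named list of [elemental_composition()]s that must include
#'   `water` and any of `lipid`, `protein`, `mineral`.
#' @param beam A [beam_model()].
#' @param table An [attenuation_table()].
#' @return Named numeric vector of alphas for the non-water molecules present.
#' @export
#' @examples
#' mols <- load_fixture("molecules")
#' alpha_from_spectrum(mols, load_fixture("spectrum_kv"), attenuation_table())
alpha_from_spectrum <- function(molecules, beam, table = attenuation_table()) {
  if (!"water" %in% names(molecules)) {
    stop("molecules must include a 'water' entry", call. = FALSE)
  }
  mu_w <- spectrum_weighted_mu_over_rho(molecules$water, beam, table)
  targets <- intersect(c("lipid", "protein", "mineral"), names(molecules))
  vapply(stats::setNames(targets, targets), function(m) {
    1000 * (spectrum_weighted_mu_over_rho(molecules[[m]], beam, table) / mu_w - 1)
  }, numeric(1))
}

#' Analytic beta coefficient of a molecule
#'
#' `beta = (Z/A)_molecule / (Z/A)_water - 1`, the closed-form counterpart to
#' the regression route of [fit_beta_from_tissues()].
#'
#' @param elem An [elemental_composition()] (or coercible named vector).
#' @return Scalar beta.
#' @export
#' @examples
#' beta_analytic(elemental_from_formula(c(Ca = 5, P = 3, O = 13, H = 1)))
beta_analytic <- function(elem) {
  electron_ratio_from_elemental(elem) - 1
}

#' Simulate the CT number of a material
#'
#' Inverse of the density/HU_rho relations: given a mass density and a
#' molecular composition, the noiseless CT number the model predicts is
#' `HU = rho * (1000 + HU_rho(comp)) - 1000`.  Used by the synthetic phantom
#' generator and the sensitivity analysis.
#'
#' @param rho Mass density, g/cc.
#' @param comp A [molecular_composition()] (or coercible named vector).
#' @param params A [model_params()].
#' @return CT number(s), HU.
#' @export
simulate_hu <- function(rho, comp, params) {
  rho * (1000 + hu_rho_from_molecular(comp, params)) - 1000
}
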