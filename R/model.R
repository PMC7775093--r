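#' Mass-density-normalized HU
#'
#' `HU_rho = (HU + 1000)/rho - 1000` removes mass density from a CT number,
#' leaving a quantity that depends only on a material's composition and the
#' imaging beam spectrum.  Unlike HU itself, `HU_rho` is an intrinsic property
#' of the material.
#'
#' Values are returned unrounded; use [round_half_away()] to compare with
#' integer-printed tables.
#'
#' @param hu CT number(s), HU.
#' @param rho Mass density(ies), g/cc; must be positive.
#' @return `HU_rho` value(s), same length as the longer input.
#' @export
#' @examples
#' hu_rho_from_hu(-63, 0.958)   # adipose surrogate, about -21.9
hu_rho_from_hu <- function(hu, rho) {
  if (!is.numeric(hu) || !is.numeric(rho)) {
    stop("hu and rho must be numeric", call. = FALSE)
  }
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("rho must be positive and finite", call. = FALSE)
  }
  (hu + 1000) / rho - 1000
}

#' Round half away from zero
#'
#' Printed CT tables round half away from zero; R's `round()` rounds half to
#' even.  Used only when comparing with displayed table values - internal
#' computation is always unrounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mass density from HU and HU_rho
#'
#' Inverts the mass-density normalization: `rho = (HU + 1000)/(HU_rho + 1000)`.
#' With `HU_rho` known a priori from composition, this turns a measured CT
#' number directly into mass density.
#'
#' In scalar use, `hu < -1000` is an error.  With `bulk = TRUE` (voxel
#' volumes, which legitimately contain air), voxels at or below -1000 HU map
#' to `rho = 0` with a warning reporting the count.
#'
#' @param hu CT number(s).
#' @param hu_rho Mass-density-normalized HU; must exceed -1000.
#' @param bulk Logical; voxel-volume semantics for sub-air HU (see Details).
#' @return Mass density(ies), g/cc.
#' @export
#' @examples
#' rho_from_hu(49, -16.87)  # muscle surrogate, about 1.067
rho_from_hu <- function(hu, hu_rho, bulk = FALSE) {
  if (any(!is.finite(hu_rho)) || any(hu_rho <= -1000)) {
    stop("hu_rho must exceed -1000", call. = FALSE)
  }
  below <- hu < -1000
  if (any(below)) {
    if (!bulk) stop("hu below -1000 (sub-air); use bulk = TRUE for volumes",
                    call. = FALSE)
    warning(sprintf("%d value(s) at or below -1000 HU mapped to rho = 0",
                    sum(hu <= -1000)), call. = FALSE)
  }
  out <- (hu + 1000) / (hu_rho + 1000)
  if (bulk) out[hu <= -1000] <- 0
  out
}

#' HU_rho of a molecular mixture
#'
#' The mass-density-normalized HU of a four-component mixture is linear in the
#' molecular mass fractions: `HU_rho = w_lipid*a1 + w_protein*a2 +
#' w_mineral*a3`.  Water contributes zero by construction (it is the HU
#' reference).
#'
#' @param comp A [molecular_composition()] (or coercible named vector).
#' @param params A [model_params()] supplying the beam-specific alphas.
#' @return `HU_rho` for the mixture.
#' @export
hu_rho_from_molecular <- function(comp, params) {
  comp <- as_molecular_composition(comp)
  stopifnot(inherits(params, "humol_params"))
  sum(unclass(comp)[names(params$alpha)] * params$alpha)
}

#' Electron ratio (rho_e / rho) of a molecular mixture
#'
#' `rho_e/rho = 1 + w_lipid*b1 + w_protein*b2 + w_mineral*b3`, the Z/A-driven
#' electron content per unit mass relative to water.  Pure water gives exactly
#' one.
#'
#' @inheritParams hu_rho_from_molecular
#' @return The dimensionless ratio rho_e/rho.
#' @export
electron_ratio_from_molecular <- function(comp, params) {
  comp <- as_molecular_composition(comp)
  stopifnot(inherits(params, "humol_params"))
  1 + sum(unclass(comp)[names(params$beta)] * params$beta)
}

#' Electron density from HU and molecular composition
#'
#' The closed-form conversion
#' `rho_e = (HU + 1000) * (1 + sum(w*beta)) / (sum(w*alpha) + 1000)`,
#' which factorizes exactly as [rho_from_hu()] times
#' [electron_ratio_from_molecular()].
#'
#' @inheritParams hu_rho_from_molecular
#' @param hu CT number(s).
#' @param bulk Passed through to the air-voxel semantics of [rho_from_hu()].
#' @return Electron density relative to water.
#' @export
#' @examples
#' p <- model_params(alpha = c(lipid = -50.8, protein = -58.1, mineral = 604.8),
#'                   beta  = c(lipid = 0.00499, protein = -0.0419, mineral = -0.113),
#'                   beam = "kv")
#' rho_e_from_hu(37.7, c(water = 0.75, protein = 0.25), p)
rho_e_from_hu <- function(hu, comp, params, bulk = FALSE) {
  denom <- hu_rho_from_molecular(comp, params) + 1000
  if (denom <= 0) stop("degenerate denominator: sum(w*alpha) + 1000 <= 0",
                       call. = FALSE)
  rho_from_hu(hu, denom - 1000, bulk = bulk) *
    electron_ratio_from_molecular(comp, params)
}

#' Electron ratio from elemental composition
#'
#' `rho_e/rho = sum_i(w_i * Z_i/A_i) / (Z/A)_water`, with both numerator and
#' the water normalization computed from the same bundled constants table.
#'
#' @param elem An [elemental_composition()] (or coercible named vector).
#' @return The dimensionless ratio rho_e/rho.
#' @export
#' @examples
#' electron_ratio_from_elemental(c(H = 0.1119, O = 0.8881))  # 1
electron_ratio_from_elemental <- function(elem) {
  if (!inherits(elem, "elemental_composition")) {
    elem <- elemental_composition(elem)
  }
  sum(unclass(elem) * z_over_a(names(elem))) / water_z_over_a()
}

#' Electron density from mass density and elemental composition
#'
#' @param rho Mass density, g/cc; positive.
#' @inheritParams electron_ratio_from_elemental
#' @return Electron density relative to water.
#' @export
rho_e_from_elemental <- function(rho, elem) {
  if (any(rho <= 0)) stop("rho must be positive", call. = FALSE)
  rho * electron_ratio_from_elemental(elem)
}
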