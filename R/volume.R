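#' Voxelwise conversion of an HU volume to density maps
#'
#' Applies the closed-form molecular conversions voxel by voxel: each labeled
#' voxel's mass density is `(HU + 1000)/(HU_rho(comp) + 1000)` and its
#' electron density is that times the composition's electron ratio.
#' Air-labeled voxels (label 0) and voxels at or below -1000 HU map to
#' `rho = rho_e = 0`; their count is reported via `message()`.
#'
#' @param hu Numeric array of CT numbers (float or integer HU; no implicit
#'   rounding is applied).
#' @param labels Integer array of the same dimensions; 0 for air/background,
#'   `i` for the i-th row of `materials`.  Any other value is an error
#'   listing the offending labels.
#' @param materials A [calibration_materials()]-style table supplying each
#'   label's molecular composition.
#' @param params A [model_params()].
#' @param beam Optional beam label; if given it must match `params$beam`
#'   (guards against converting a kV scan with MV coefficients).
#' @return List with numeric arrays `rho` and `rho_e` and the count
#'   `n_zeroed` of air/sub-air voxels.
#' @export
convert_volume <- function(hu, labels, materials, params, beam = NULL) {
  if (!inherits(materials, "humol_materials")) {
    materials <- calibration_materials(materials)
  }
  stopifnot(inherits(params, "humol_params"))
  if (!is.null(beam) && !identical(beam, params$beam)) {
    stop(sprintf("beam label mismatch: volume is '%s' but params were calibrated for '%s'",
                 beam, params$beam), call. = FALSE)
  }
  if (!identical(dim(hu), dim(labels))) {
    stop("hu and labels must have identical dimensions", call. = FALSE)
  }
  lab <- as.integer(labels)
  bad <- setdiff(unique(lab), 0:nrow(materials))
  if (length(bad)) {
    stop("unlabeled/unknown label values: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  }
  hur <- vapply(seq_len(nrow(materials)), function(i) {
    hu_rho_from_molecular(material_composition(materials, i), params)
  }, numeric(1))
  ratio <- vapply(seq_len(nrow(materials)), function(i) {
    electron_ratio_from_molecular(material_composition(materials, i), params)
  }, numeric(1))
  huv <- as.numeric(hu)
  rho <- numeric(length(huv))
  live <- lab > 0L & huv > -1000
  rho[live] <- (huv[live] + 1000) / (hur[lab[live]] + 1000)
  rho_e <- numeric(length(huv))
  rho_e[live] <- rho[live] * ratio[lab[live]]
  n_zeroed <- sum(!live)
  if (n_zeroed > 0) {
    message(sprintf("%d voxel(s) set to rho = rho_e = 0 (air label or HU <= -1000)",
                    n_zeroed))
  }
  list(rho = array(rho, dim(hu)), rho_e = array(rho_e, dim(hu)),
       n_zeroed = n_zeroed)
}

#' Per-material comparison report against ground truth
#'
#' Re-derives mass density and electron density for each material from its
#' measured CT number by the molecular-composition method and, optionally, by
#' the clinical piecewise-linear baseline, and tabulates percent errors
#' against ground truth (`100 * (estimated - truth) / truth`, matching the
#' usual phantom-report layout).
#'
#' @param truth Data frame with columns `name`, `omega_water`, `omega_lipid`,
#'   `omega_protein`, `omega_mineral` (fractions or percent), `rho_truth`,
#'   `rho_e_truth`.
#' @param hu Numeric vector of measured CT numbers, one per row of `truth`.
#' @param params A [model_params()].
#' @param lut_rho,lut_rho_e Optional [build_piecewise_lut()] LUTs supplying
#'   the baseline method.
#' @param digits Rounding applied to the printed-style columns (default 3 for
#'   densities, 1 for percent errors uses `digits - 2`).
#' @return Data frame, one row per material.
#' @export
run_report <- function(truth, hu, params, lut_rho = NULL, lut_rho_e = NULL,
                       digits = 3) {
  stopifnot(nrow(truth) == length(hu))
  om <- c("omega_water", "omega_lipid", "omega_protein", "omega_mineral")
  ww <- truth[om]
  if (all(abs(rowSums(ww) - 100) < 1)) ww <- ww / 100
  out <- data.frame(name = truth$name, hu = hu,
                    rho_truth = truth$rho_truth,
                    rho_e_truth = truth$rho_e_truth,
                    stringsAsFactors = FALSE)
  n <- nrow(truth)
  rho_mol <- rho_e_mol <- numeric(n)
  for (i in seq_len(n)) {
    comp <- as_molecular_composition(stats::setNames(
      as.numeric(ww[i, ]), c("water", "lipid", "protein", "mineral")))
    rho_mol[i] <- rho_from_hu(hu[i], hu_rho_from_molecular(comp, params))
    rho_e_mol[i] <- rho_mol[i] * electron_ratio_from_molecular(comp, params)
  }
  out$rho_mol <- round_half_away(rho_mol, digits)
  out$rho_e_mol <- round_half_away(rho_e_mol, digits)
  out$rho_mol_err_pct <- round_half_away(
    100 * (rho_mol - out$rho_truth) / out$rho_truth, 1)
  out$rho_e_mol_err_pct <- round_half_away(
    100 * (rho_e_mol - out$rho_e_truth) / out$rho_e_truth, 1)
  if (!is.null(lut_rho)) {
    v <- predict(lut_rho, hu)
    out$rho_lut <- round_half_away(v, digits)
    out$rho_lut_err_pct <- round_half_away(
      100 * (v - out$rho_truth) / out$rho_truth, 1)
  }
  if (!is.null(lut_rho_e)) {
    v <- predict(lut_rho_e, hu)
    out$rho_e_lut <- round_half_away(v, digits)
    out$rho_e_lut_err_pct <- round_half_away(
      100 * (v - out$rho_e_truth) / out$rho_e_truth, 1)
  }
  attr(out, "params_beam") <- params$beam
  attr(out, "params_method") <- params$method
  out
}
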