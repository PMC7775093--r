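#' Validate a calibration-material table
#'
#' Calibration materials are phantom inserts with an assumed molecular
#' composition, a known mass density, and a measured CT number for each
#' imaging beam.  The expected tabular schema is columns `name`,
#' `omega_water`, `omega_lipid`, `omega_protein`, `omega_mineral`
#' (fractions or percentages; percentages are detected and divided by 100),
#' `rho`, and one `hu_<beam>` column per beam (e.g. `hu_kv`, `hu_mv`).
#'
#' @param df Data frame in the material schema.
#' @return The validated data frame (fractions normalized), classed
#'   `humol_materials`.
#' @export
calibration_materials <- function(df) {
  need <- c("name", "omega_water", "omega_lipid", "omega_protein",
            "omega_mineral", "rho")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("material table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!any(grepl("^hu_", names(df)))) {
    stop("material table needs at least one hu_<beam> column", call. = FALSE)
  }
  om <- c("omega_water", "omega_lipid", "omega_protein", "omega_mineral")
  sums <- rowSums(df[om])
  if (all(abs(sums - 100) < 1)) df[om] <- df[om] / 100  # percent table
  for (i in seq_len(nrow(df))) {
    w <- as.numeric(df[i, om])
    cc <- molecular_composition(w[1], w[2], w[3], w[4])
    df[i, om] <- as.numeric(unclass(cc))
  }
  if (any(df$rho <= 0)) stop("rho must be positive", call. = FALSE)
  class(df) <- c("humol_materials", class(df))
  df
}

#' Phantom-scan calibration of the alpha coefficients
#'
#' The phantom route: compute each material's mass-density-normalized HU from
#' its measured CT number and known density, then fit
#' `HU_rho ~ 0 + omega_lipid + omega_protein + omega_mineral` by ordinary
#' (unweighted) least squares.  There is no intercept anywhere - pure water is
#' the zero reference of the model, so the fit is forced through it.
#'
#' Materials whose lipid/protein/mineral fractions are all zero (water rows)
#' exert no leverage on a no-intercept fit; their residual equals their own
#' `HU_rho`.
#'
#' @param materials A [calibration_materials()] table (or coercible data
#'   frame).
#' @param beam Beam label selecting the `hu_<beam>` column.
#' @return A list of class `humol_alpha_fit`: `alpha` (named coefficients),
#'   `beam`, `fitted`, `residuals`, `r_squared` (no-intercept convention),
#'   `se` (coefficient standard errors), `hu_rho` (the regressand) and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' fit_alpha_from_phantom(load_fixture("table1"), beam = "kv")$alpha
fit_alpha_from_phantom <- function(materials, beam) {
  if (!inherits(materials, "humol_materials")) {
    materials <- calibration_materials(materials)
  }
  hucol <- paste0("hu_", beam)
  if (!hucol %in% names(materials)) {
    stop("no column ", hucol, " in material table", call. = FALSE)
  }
  y <- hu_rho_from_hu(materials[[hucol]], materials$rho)
  X <- as.matrix(materials[c("omega_lipid", "omega_protein", "omega_mineral")])
  colnames(X) <- c("lipid", "protein", "mineral")
  if (qr(X)$rank < 3L) {
    nz <- colSums(X != 0)
    stop("rank-deficient design: lipid/protein/mineral columns are collinear ",
         "or empty (non-zero rows: ",
         paste(sprintf("%s=%d", colnames(X), nz), collapse = ", "), ")",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ 0 + X)
  alpha <- stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
  structure(list(
    alpha = alpha,
    beam = beam,
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(stats::resid(fit)),
    r_squared = summary(fit)$r.squared,
    se = stats::setNames(summary(fit)$coefficients[, "Std. Error"],
                         colnames(X)),
    hu_rho = y,
    materials = materials$name,
    lm = fit
  ), class = "humol_alpha_fit")
}

#' @export
print.humol_alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha calibration, beam %s, %d materials>\n",
              x$beam, length(x$hu_rho)))
  print(round(x$alpha, 2))
  cat(sprintf("  R^2 = %.4f, max |residual| = %.2f HU_rho\n",
              x$r_squared, max(abs(x$residuals))))
  invisible(x)
}

#' Regression calibration of the beta coefficients
#'
#' Computes each tissue's electron ratio rho_e/rho from its elemental
#' composition and regresses the excess over one on the molecular
#' lipid/protein/mineral fractions with the intercept fixed at one
#' (equivalently: no-intercept regression of `rho_e/rho - 1`).
#'
#' @param tissues Data frame with columns `omega_lipid`, `omega_protein`,
#'   `omega_mineral` and a list-column `elemental` of
#'   [elemental_composition()]s (the bundled `"tissues"` fixture has this
#'   shape).
#' @return A list of class `humol_beta_fit`: `beta`, `r_squared`, `rmse`,
#'   `residuals`, and the electron ratios used.
#' @export
#' @examples
#' fit_beta_from_tissues(load_fixture("tissues"))$beta
fit_beta_from_tissues <- function(tissues) {
  need <- c("omega_lipid", "omega_protein", "omega_mineral", "elemental")
  missing <- setdiff(need, names(tissues))
  if (length(missing)) {
    stop("tissue table lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- vapply(tissues$elemental, electron_ratio_from_elemental, numeric(1)) - 1
  X <- as.matrix(tissues[c("omega_lipid", "omega_protein", "omega_mineral")])
  colnames(X) <- c("lipid", "protein", "mineral")
  if (qr(X)$rank < 3L) {
    stop("rank-deficient design: tissues do not span lipid/protein/mineral",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ 0 + X)
  beta <- stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
  res <- as.numeric(stats::resid(fit))
  structure(list(
    beta = beta,
    r_squared = summary(fit)$r.squared,
    rmse = sqrt(mean(res^2)),
    residuals = res,
    electron_ratio = y + 1,
    lm = fit
  ), class = "humol_beta_fit")
}

#' @export
print.humol_beta_fit <- function(x, ...) {
  cat(sprintf("<beta calibration, %d tissues> R^2 = %.4f, RMSE = %.2g\n",
              length(x$residuals), x$r_squared, x$rmse))
  print(signif(x$beta, 4))
  invisible(x)
}

#' Clinical piecewise-linear HU calibration baseline
#'
#' The clinical standard: sort the calibration materials by measured CT
#' number and interpolate the target quantity (mass density or electron
#' density) linearly between breakpoints.  Duplicate HU breakpoints with
#' conflicting targets are averaged (with a message).  Beyond the calibrated
#' range the terminal segments are continued linearly; queries more than 10%
#' of the calibrated HU span beyond either end draw a warning.
#'
#' @param materials A [calibration_materials()] table; for `target =
#'   "rho_e"` it must also carry a `rho_e` column (ground-truth or
#'   manufacturer values).
#' @param beam Beam label selecting the `hu_<beam>` column.
#' @param target `"rho"` or `"rho_e"`.
#' @return A `humol_lut` object; evaluate it with [predict()].
#' @export
#' @examples
#' lut <- build_piecewise_lut(load_fixture("table1"), "kv", "rho_e")
#' predict(lut, 49)  # muscle breakpoint
build_piecewise_lut <- function(materials, beam, target = c("rho", "rho_e")) {
  target <- match.arg(target)
  if (!inherits(materials, "humol_materials")) {
    materials <- calibration_materials(materials)
  }
  hucol <- paste0("hu_", beam)
  if (!hucol %in% names(materials)) {
    stop("no column ", hucol, " in material table", call. = FALSE)
  }
  if (!target %in% names(materials)) {
    stop("material table lacks target column ", target, call. = FALSE)
  }
  hu <- materials[[hucol]]
  val <- materials[[target]]
  if (length(hu) < 2) stop("need at least two materials", call. = FALSE)
  o <- order(hu)
  hu <- hu[o]; val <- val[o]
  if (anyDuplicated(hu)) {
    agg <- tapply(val, hu, mean)
    message(sprintf("averaged %d duplicate HU breakpoint(s)",
                    length(hu) - length(agg)))
    hu <- as.numeric(names(agg)); val <- as.numeric(agg)
  }
  structure(list(hu = hu, value = val, beam = beam, target = target),
            class = "humol_lut")
}

#' @export
print.humol_lut <- function(x, ...) {
  cat(sprintf("<piecewise-linear LUT: HU(%s) -> %s, %d breakpoints on [%g, %g]>\n",
              x$beam, x$target, length(x$hu), min(x$hu), max(x$hu)))
  invisible(x)
}

#' Evaluate a piecewise-linear calibration LUT
#'
#' @param object A `humol_lut` from [build_piecewise_lut()].
#' @param hu CT number(s) to convert.
#' @param ... Unused.
#' @return Interpolated target values.
#' @export
predict.humol_lut <- function(object, hu, ...) {
  span <- diff(range(object$hu))
  lo <- min(object$hu) - 0.1 * span
  hi <- max(object$hu) + 0.1 * span
  if (any(hu < lo | hu > hi)) {
    warning(sprintf("%d quer(ies) more than 10%% beyond the calibrated HU range",
                    sum(hu < lo | hu > hi)), call. = FALSE)
  }
  out <- stats::approx(object$hu, object$value, xout = hu, rule = 1)$y
  # linear continuation of the terminal segments
  n <- length(object$hu)
  below <- hu < object$hu[1]
  above <- hu > object$hu[n]
  if (any(below)) {
    s <- (object$value[2] - object$value[1]) / (object$hu[2] - object$hu[1])
    out[below] <- object$value[1] + s * (hu[below] - object$hu[1])
  }
  if (any(above)) {
    s <- (object$value[n] - object$value[n - 1]) /
      (object$hu[n] - object$hu[n - 1])
    out[above] <- object$value[n] + s * (hu[above] - object$hu[n])
  }
  out
}

#' Flag calibration materials with non-biological chlorine content
#'
#' Tissue-surrogate inserts containing >= 1% chlorine by mass (a threshold
#' met by some lung surrogates) behave unlike biological tissues under the
#' molecular model and should normally be excluded from calibration fits.
#' This function only flags; exclusion is the caller's decision, and flagged
#' materials are kept in reports for auditability.
#'
#' @param elementals Named list of [elemental_composition()]s (names are the
#'   material names).
#' @param threshold Chlorine mass-fraction threshold, inclusive.  Default
#'   0.01.
#' @return Data frame with columns `name`, `chlorine`, `flagged`.
#' @export
qc_flag_materials <- function(elementals, threshold = 0.01) {
  cl <- vapply(elementals, function(e) {
    e <- unclass(e)
    if ("Cl" %in% names(e)) e[["Cl"]] else 0
  }, numeric(1))
  data.frame(name = names(elementals),
             chlorine = as.numeric(cl),
             flagged = as.numeric(cl) >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
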