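#' Model coefficients for the molecular HU/density relationship
#'
#' Bundles the beam-specific `alpha` coefficients (the mass-density-normalized
#' HU of the pure lipid, protein and mineral components, in HU units) and the
#' beam-independent `beta` coefficients (the fractional excess of each
#' component's Z/A ratio over water's).  Water's coefficients are identically
#' zero by construction and are not stored.
#'
#' @param alpha Named numeric vector `c(lipid=, protein=, mineral=)`, HU units.
#' @param beta Named numeric vector `c(lipid=, protein=, mineral=)`,
#'   dimensionless.
#' @param beam Label of the beam the alphas were calibrated for (e.g. `"kv"`).
#' @param method Optional note on how the alphas were obtained
#'   (`"spectrum"` or `"phantom"`).
#' @return An object of class `humol_params`.
#' @export
model_params <- function(alpha, beta, beam = "unspecified", method = NA_character_) {
  nm <- c("lipid", "protein", "mineral")
  for (v in list(alpha = alpha, beta = beta)) {
    if (length(v) != 3 || is.null(names(v)) || !setequal(names(v), nm)) {
      stop("alpha and beta must each be length-3 vectors named lipid/protein/mineral",
           call. = FALSE)
    }
  }
  structure(list(alpha = alpha[nm], beta = beta[nm],
                 beam = beam, method = method),
            class = "humol_params")
}

#' @export
print.humol_params <- function(x, ...) {
  cat(sprintf("<humol model parameters> beam=%s method=%s\n", x$beam,
              ifelse(is.na(x$method), "?", x$method)))
  cat("  alpha (HU):      ", paste(sprintf("%s=%.2f", names(x$alpha), x$alpha),
                                   collapse = "  "), "\n")
  cat("  beta (unitless): ", paste(sprintf("%s=%.5f", names(x$beta), x$beta),
                                   collapse = "  "), "\n")
  invisible(x)
}

#' Reference beta coefficients
#'
#' Electron-ratio coefficients for lipid, protein and mineral obtained by
#' regressing the mass-density-normalized electron density of a standard
#' human-tissue compilation on its molecular composition (R^2 = 0.998).
#' These are beam-independent; they are shipped as reference constants and
#' can be re-derived from a tissue table with [fit_beta_from_tissues()].
#'
#' @return Named numeric vector `c(lipid, protein, mineral)`.
#' @export
reference_beta <- function() {
  c(lipid = 0.00499, protein = -0.0419, mineral = -0.113)
}

#' Reference model parameters for the bundled beam pair
#'
#' Returns ready-to-use [model_params()] for the 120 kVp (`"kv"`) or 3.5 MV
#' (`"mv"`) beam: the alphas are recomputed at call time by the phantom-scan
#' calibration route ([fit_alpha_from_phantom()]) on the bundled calibration
#' phantom table, and the betas are [reference_beta()].
#'
#' @param beam `"kv"` or `"mv"`.
#' @return A `humol_params` object.
#' @export
reference_params <- function(beam = c("kv", "mv")) {
  beam <- match.arg(beam)
  fit <- fit_alpha_from_phantom(load_fixture("table1"), beam = beam)
  model_params(alpha = fit$alpha, beta = reference_beta(),
               beam = beam, method = "phantom")
}

#' Read/write model parameters as JSON
#'
#' @param params A `humol_params` object.
#' @param path File path.
#' @return `read_params` returns a `humol_params`; `write_params` its path,
#'   invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "humol_params"))
  jsonlite::write_json(
    list(beam = params$beam, method = params$method,
         alpha = as.list(params$alpha), beta = as.list(params$beta)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(alpha = unlist(x$alpha), beta = unlist(x$beta),
               beam = x$beam,
               method = if (is.null(x$method)) NA_character_ else x$method)
}
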