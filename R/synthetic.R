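#' Specification of a synthetic voxel phantom
#'
#' Describes a rectangular voxel grid containing box-shaped regions of
#' calibration materials, plus a Gaussian HU noise level and a seed.  Stands
#' in for a scanned physical phantom so every pipeline stage is testable
#' without image data.
#'
#' @param materials A [calibration_materials()]-style data frame (only
#'   `name`, the `omega_*` columns and `rho` are used).
#' @param regions List of regions, each `list(material = <name>, from =
#'   c(i, j, k), to = c(i, j, k))` in voxel coordinates (inclusive).
#' @param dim Integer grid dimensions, length 3.
#' @param noise_sd Standard deviation of additive Gaussian HU noise (>= 0).
#' @param seed Integer RNG seed, or `NULL`.
#' @return A `humol_phantom_spec` object.
#' @export
phantom_spec <- function(materials, regions, dim, noise_sd = 0, seed = NULL) {
  if (!inherits(materials, "humol_materials")) {
    materials <- calibration_materials(materials)
  }
  stopifnot(length(dim) == 3, all(dim >= 1), noise_sd >= 0)
  occupied <- array(FALSE, dim)
  for (r in regions) {
    if (!all(c("material", "from", "to") %in% names(r))) {
      stop("each region needs material, from, to", call. = FALSE)
    }
    if (!r$material %in% materials$name) {
      stop("region material not in table: ", r$material, call. = FALSE)
    }
    if (any(r$from < 1) || any(r$to > dim) || any(r$from > r$to)) {
      stop("region outside grid or inverted: ", r$material, call. = FALSE)
    }
    sel <- occupied[r$from[1]:r$to[1], r$from[2]:r$to[2], r$from[3]:r$to[3]]
    if (any(sel)) stop("overlapping regions at material ", r$material,
                       call. = FALSE)
    occupied[r$from[1]:r$to[1], r$from[2]:r$to[2], r$from[3]:r$to[3]] <- TRUE
  }
  structure(list(materials = materials, regions = regions, dim = dim,
                 noise_sd = noise_sd, seed = seed),
            class = "humol_phantom_spec")
}

#' Generate a synthetic HU volume from a phantom specification
#'
#' Each region's noiseless CT number is the model prediction
#' [simulate_hu()]`(rho, composition, params)`; Gaussian noise of the
#' specified SD is then added under the specified seed (bit-identical across
#' repeated calls).  Background voxels are air at -1000 HU, label 0.
#'
#' @param spec A [phantom_spec()].
#' @param params A [model_params()].
#' @return List with `hu` (numeric array), `labels` (integer array; 0 = air,
#'   i = i-th material row), and `truth` (data frame of per-material ground
#'   truth: `rho`, `rho_e`, noiseless `hu`, voxel count).
#' @export
generate_phantom <- function(spec, params) {
  stopifnot(inherits(spec, "humol_phantom_spec"))
  m <- spec$materials
  hu0 <- vapply(seq_len(nrow(m)), function(i) {
    simulate_hu(m$rho[i], material_composition(m, i), params)
  }, numeric(1))
  rho_e <- vapply(seq_len(nrow(m)), function(i) {
    m$rho[i] * electron_ratio_from_molecular(material_composition(m, i), params)
  }, numeric(1))
  labels <- array(0L, spec$dim)
  hu <- array(-1000, spec$dim)
  for (r in spec$regions) {
    idx <- match(r$material, m$name)
    labels[r$from[1]:r$to[1], r$from[2]:r$to[2], r$from[3]:r$to[3]] <- idx
    hu[r$from[1]:r$to[1], r$from[2]:r$to[2], r$from[3]:r$to[3]] <- hu0[idx]
  }
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    noise <- array(stats::rnorm(prod(spec$dim), 0, spec$noise_sd), spec$dim)
    hu[labels > 0] <- hu[labels > 0] + noise[labels > 0]
  }
  truth <- data.frame(name = m$name, rho = m$rho, rho_e = rho_e,
                      hu_noiseless = hu0,
                      n_voxels = tabulate(labels, nbins = nrow(m)),
                      stringsAsFactors = FALSE)
  list(hu = hu, labels = labels, truth = truth)
}

# composition of row i of a material table
material_composition <- function(materials, i) {
  as_molecular_composition(c(
    water = materials$omega_water[i], lipid = materials$omega_lipid[i],
    protein = materials$omega_protein[i], mineral = materials$omega_mineral[i]))
}

#' Sample perturbed tissue compositions
#'
#' Draws compositions scattered around a base composition, emulating the
#' natural 5-10% relative variation of soft-tissue molecular makeup.  Each
#' non-zero component is jittered multiplicatively by `1 + variation * u`
#' with `u ~ Uniform(-1, 1)` and the result renormalized onto the simplex
#' (components that are zero in the base stay zero).
#'
#' @param base A [molecular_composition()] (or coercible named vector).
#' @param variation Relative variation amplitude in `[0, 1)`.
#' @param n Number of draws.
#' @param seed Optional RNG seed.
#' @return Data frame of `n` rows with columns water/lipid/protein/mineral,
#'   each row a valid composition.
#' @export
#' @examples
#' sample_tissue_compositions(c(water = 0.75, lipid = 0.05, protein = 0.2),
#'                            variation = 0.1, n = 5, seed = 1)
sample_tissue_compositions <- function(base, variation, n, seed = NULL) {
  base <- as_molecular_composition(base)
  if (variation < 0 || variation >= 1) {
    stop("variation must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  b <- unclass(base)
  u <- matrix(stats::runif(n * 4, -1, 1), nrow = n)
  w <- sweep(1 + variation * u, 2, b, `*`)
  w <- w / rowSums(w)
  out <- as.data.frame(w)
  names(out) <- names(b)
  out
}
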