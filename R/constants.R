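#' Atomic constants table
#'
#' Standard atomic numbers and CIAAW-style conventional atomic weights for the
#' elements occurring in biological tissues, tissue surrogates, and beam
#' filtration.  This single table is used everywhere in the package, including
#' for the water Z/A reference, so that every electron-density ratio is
#' self-consistent.
#'
#' @return A data frame with columns `symbol`, `Z` (atomic number) and `A`
#'   (atomic mass, g/mol).
#' @export
#' @examples
#' atomic_constants()
atomic_constants <- function() {
  data.frame(
    symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S",
               "Cl", "Ar", "K", "Ca", "Fe", "Cu", "Zn", "I"),
    Z = c(1L, 6L, 7L, 8L, 9L, 11L, 12L, 14L, 15L, 16L,
          17L, 18L, 19L, 20L, 26L, 29L, 30L, 53L),
    A = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305, 28.085,
          30.974, 32.06, 35.45, 39.948, 39.098, 40.078, 55.845, 63.546,
          65.38, 126.904),
    stringsAsFactors = FALSE
  )
}

#' Z/A ratio for chemical elements
#'
#' @param symbols Character vector of element symbols.
#' @return Numeric vector of Z/A (electrons per g/mol).
#' @export
z_over_a <- function(symbols) {
  tab <- atomic_constants()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tab$Z[idx] / tab$A[idx]
}

#' Z/A of liquid water
#'
#' Computed from the bundled constants table via the H2O stoichiometry rather
#' than hard-coded, so the normalization is consistent with every other Z/A in
#' the package.
#'
#' @return Scalar Z/A of water (approximately 10/18.015).
#' @export
water_z_over_a <- function() {
  w <- elemental_from_formula(c(H = 2, O = 1))
  sum(unclass(w) * z_over_a(names(w)))
}
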