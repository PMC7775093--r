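#' Four-component molecular composition
#'
#' Biological tissues are modeled as mass-fraction mixtures of four molecular
#' components: water, lipid, protein and mineral (hydroxyapatite).  A
#' `molecular_composition` is a named numeric vector of the four mass
#' fractions, validated to lie in \[0, 1\] and to sum to one.
#'
#' Inputs whose fractions sum to within `tol` of one (hand-entered tables are
#' often off in the last digit) are renormalized with a message; larger
#' deviations are an error.
#'
#' @param water,lipid,protein,mineral Mass fractions (dimensionless).
#' @param tol Permitted deviation of the fraction sum from one before
#'   renormalization is refused.  Default `1e-3`.
#' @return A `molecular_composition` object.
#' @export
#' @examples
#' molecular_composition(water = 0.75, protein = 0.25)
molecular_composition <- function(water = 0, lipid = 0, protein = 0,
                                  mineral = 0, tol = 1e-3) {
  w <- c(water = unname(water), lipid = unname(lipid),
         protein = unname(protein), mineral = unname(mineral))
  if (anyNA(w) || !is.numeric(w)) {
    stop("molecular fractions must be numeric and non-missing", call. = FALSE)
  }
  if (any(w < 0) || any(w > 1 + tol)) {
    stop("molecular fractions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(w)
  if (abs(s - 1) > tol) {
    stop(sprintf("molecular fractions sum to %.6f, outside 1 +/- %g", s, tol),
         call. = FALSE)
  }
  if (abs(s - 1) > 1e-6) {
    message(sprintf("renormalizing molecular fractions (sum was %.6f)", s))
    w <- w / s
  } else if (s != 1) {
    w <- w / s
  }
  structure(w, class = "molecular_composition")
}

#' Coerce a named vector to a molecular composition
#'
#' @param x Named numeric vector with names among water/lipid/protein/mineral,
#'   or a `molecular_composition`.
#' @param tol Passed to [molecular_composition()].
#' @return A `molecular_composition`.
#' @export
as_molecular_composition <- function(x, tol = 1e-3) {
  if (inherits(x, "molecular_composition")) return(x)
  nm <- c("water", "lipid", "protein", "mineral")
  if (is.null(names(x)) || !all(names(x) %in% nm)) {
    stop("names must be among water/lipid/protein/mineral", call. = FALSE)
  }
  full <- stats::setNames(numeric(4), nm)
  full[names(x)] <- x
  molecular_composition(full["water"], full["lipid"], full["protein"],
                        full["mineral"], tol = tol)
}

#' @export
print.molecular_composition <- function(x, ...) {
  cat("<molecular composition>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Elemental composition by mass
#'
#' A named numeric vector of elemental mass fractions.  Every element must be
#' present in [atomic_constants()]; unknown symbols are an error naming the
#' offending symbol.  Fraction sums off by at most `tol` are renormalized.
#'
#' @param fractions Named numeric vector, names are element symbols.
#' @param tol Permitted deviation of the sum from one.  Default `1e-3`.
#' @return An `elemental_composition` object.
#' @export
#' @examples
#' elemental_composition(c(H = 0.1119, O = 0.8881))
elemental_composition <- function(fractions, tol = 1e-3) {
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    stop("elemental fractions must be named by element symbol", call. = FALSE)
  }
  z_over_a(names(fractions))  # errors on unknown symbols
  if (any(fractions < 0) || any(fractions > 1 + tol)) {
    stop("elemental fractions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(fractions)
  if (abs(s - 1) > tol) {
    stop(sprintf("elemental fractions sum to %.6f, outside 1 +/- %g", s, tol),
         call. = FALSE)
  }
  if (s != 1) fractions <- fractions / s
  structure(fractions, class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition>\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Elemental mass fractions from a stoichiometric formula
#'
#' Converts atom counts (e.g. `c(Ca = 5, P = 3, O = 13, H = 1)` for
#' hydroxyapatite) to mass fractions using the bundled atomic weights.
#'
#' @param counts Named numeric vector of atoms per formula unit.
#' @return An `elemental_composition`.
#' @export
#' @examples
#' elemental_from_formula(c(H = 2, O = 1))  # water
elemental_from_formula <- function(counts) {
  tab <- atomic_constants()
  idx <- match(names(counts), tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(names(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mass <- counts * tab$A[idx]
  structure(mass / sum(mass), class = "elemental_composition")
}

#' Mix molecule elemental compositions by molecular mass fractions
#'
#' Given a four-component molecular composition and a molecule library (named
#' list of `elemental_composition`s with entries water/lipid/protein/mineral),
#' returns the elemental composition of the mixture.
#'
#' @param comp A [molecular_composition()].
#' @param molecules Named list of elemental compositions; defaults to the
#'   bundled molecule library.
#' @return An `elemental_composition`.
#' @export
mix_elemental <- function(comp, molecules = load_fixture("molecules")) {
  comp <- as_molecular_composition(comp)
  need <- names(comp)[unclass(comp) > 0]
  missing <- setdiff(need, names(molecules))
  if (length(missing)) {
    stop("molecule library lacks entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  acc <- numeric(0)
  for (m in need) {
    el <- unclass(molecules[[m]]) * unclass(comp)[m]
    for (sym in names(el)) {
      acc[sym] <- if (sym %in% names(acc)) acc[sym] + el[[sym]] else el[[sym]]
    }
  }
  elemental_composition(acc)
}
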