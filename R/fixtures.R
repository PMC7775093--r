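#' Bundled data fixtures
#'
#' Loads one of the package's built-in data sets:
#' \describe{
#'   \item{`table1`}{The CIRS tissue-surrogate calibration phantom: nine
#'     inserts with assumed molecular compositions, manufacturer mass density
#'     and electron density, and measured CT numbers for the kV and MV beams.
#'     Returned as a [calibration_materials()] table.  The `rho_e` column is
#'     manufacturer-derived fixture data; it cannot be recomputed from the
#'     molecular columns and never is.}
#'   \item{`table2`}{The in-house tissue-mimicking phantom: four materials
#'     mixed from water, coconut oil, gelatin and hydroxyapatite, with
#'     ground-truth density/electron density (and uncertainties) and the
#'     imaging-derived values by the piecewise-linear baseline (`*_kv1`,
#'     `*_mv1`) and the molecular method (`*_kv5`, `*_mv5`).}
#'   \item{`molecules`}{Named list of [elemental_composition()]s for the four
#'     molecule classes.  Water and hydroxyapatite are built
#'     stoichiometrically (H2O, Ca5(PO4)3OH); lipid and protein use the
#'     bundled representative mass fractions.}
#'   \item{`tissues`}{A synthetic reference-tissue table for the beta
#'     regression: molecular fractions plus a list-column `elemental` of
#'     compositions derived by mixing the molecule library.}
#'   \item{`attenuation`}{The bundled XCOM-style elemental attenuation table
#'     (see [attenuation_table()]).}
#'   \item{`spectrum_kv`}{The bundled heavily filtered 120 kVp example
#'     spectrum as a [beam_model()] (see [filtered_kramers_spectrum()]).}
#' }
#'
#' @param name One of `"table1"`, `"table2"`, `"molecules"`, `"tissues"`,
#'   `"attenuation"`, `"spectrum_kv"`.
#' @return See Description.
#' @export
#' @examples
#' nrow(load_fixture("table1"))
load_fixture <- function(name) {
  path <- function(f) system.file("extdata", f, package = "humol",
                                  mustWork = TRUE)
  switch(name,
    table1 = {
      df <- utils::read.csv(path("table1_cirs.csv"), comment.char = "#",
                            check.names = FALSE)
      calibration_materials(df)
    },
    table2 = utils::read.csv(path("table2_inhouse.csv"), comment.char = "#",
                             check.names = FALSE),
    molecules = {
      df <- utils::read.csv(path("molecules_empirical.csv"),
                            comment.char = "#")
      emp <- lapply(split(df, df$molecule), function(d) {
        elemental_composition(stats::setNames(d$mass_fraction, d$element))
      })
      list(water = elemental_from_formula(c(H = 2, O = 1)),
           lipid = emp$lipid,
           protein = emp$protein,
           mineral = hydroxyapatite())
    },
    tissues = {
      df <- utils::read.csv(path("tissues_synthetic.csv"), comment.char = "#")
      mols <- load_fixture("molecules")
      df$elemental <- lapply(seq_len(nrow(df)), function(i) {
        mix_elemental(as_molecular_composition(c(
          water = df$omega_water[i], lipid = df$omega_lipid[i],
          protein = df$omega_protein[i], mineral = df$omega_mineral[i])),
          mols)
      })
      df
    },
    attenuation = attenuation_table(),
    spectrum_kv = read_spectrum(path("spectrum_kv120.csv"), label = "kV120"),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}

#' Stoichiometric hydroxyapatite
#'
#' Elemental composition of Ca5(PO4)3OH, the mineral axis of the
#' four-component tissue model (Ca:P molar ratio 5:3).
#'
#' @return An [elemental_composition()].
#' @export
hydroxyapatite <- function() {
  elemental_from_formula(c(Ca = 5, P = 3, O = 13, H = 1))
}
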