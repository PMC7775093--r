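#' Read a material table from CSV or JSON
#'
#' Dispatches on the file extension.  CSV files follow the bundled phantom
#' schema (see [calibration_materials()]); JSON files hold an array of
#' objects with the same field names.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A [calibration_materials()] table.
#' @export
read_materials <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, comment.char = "#", check.names = FALSE),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)),
    stop("unsupported material table format: .", ext, call. = FALSE))
  calibration_materials(df)
}

#' Write a material table
#'
#' @param materials A material data frame.
#' @param path Output path (`.csv` or `.json`).
#' @return The path, invisibly.
#' @export
write_materials <- function(materials, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.csv(materials, path, row.names = FALSE),
    json = jsonlite::write_json(materials, path, dataframe = "rows",
                                digits = NA),
    stop("unsupported material table format: .", ext, call. = FALSE))
  invisible(path)
}

#' Serialize a piecewise-linear LUT as JSON
#'
#' @param lut A `humol_lut` from [build_piecewise_lut()].
#' @param path File path.
#' @return `read_lut` returns the LUT; `write_lut` the path, invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "humol_lut"))
  jsonlite::write_json(unclass(lut), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hu = as.numeric(x$hu), value = as.numeric(x$value),
                 beam = x$beam, target = x$target),
            class = "humol_lut")
}
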