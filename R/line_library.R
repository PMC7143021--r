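#' The 43-line LIBS emission library
#'
#' Returns the fixed library of emission lines used as regression variables
#' throughout the pipeline: atomic lines of C, Si, Mg, Ca, Na, K, N, H and O,
#' the CN violet-band heads, and four unidentified lines, covering the
#' 240-860 nm spectral window of a typical echelle LIBS instrument.
#'
#' @return A data.frame with 43 rows and columns `index` (1..43),
#'   `wavelength_nm` (strictly ascending) and `species` (e.g. `"Mg II"`,
#'   `"CN 0-0"`, `"Unknown"`).
#' @examples
#' lines <- libs_line_library()
#' nrow(lines)                     # 43
#' lines[lines$species == "Na I", ]
#' @export
libs_line_library <- function() {
  wl <- c(247.88, 250.72, 251.45, 251.64, 251.94, 252.44, 252.88,
          279.58, 280.30, 285.25, 288.20,
          385.07, 385.49, 386.17, 387.13, 388.33,
          393.37, 396.89, 422.70,
          589.03, 589.64, 656.33, 715.77,
          742.45, 744.30, 746.92, 748.47,
          766.57, 769.97, 777.47,
          794.83, 795.17,
          818.57, 818.86, 820.10, 821.14, 821.68, 822.28, 822.43,
          824.32, 844.73, 856.86, 859.49)
  sp <- c("C I", "Si I", "Si I", "Si I", "Si I", "Si I", "Si I",
          "Mg II", "Mg II", "Mg I", "Si I",
          "CN 4-4", "CN 3-3", "CN 2-2", "CN 1-1", "CN 0-0",
          "Ca II", "Ca II", "Ca I",
          "Na I", "Na I", "H\u03b1", "O I",
          "N I", "N I", "N I", "Unknown",
          "K I", "K I", "O I",
          "Unknown", "Unknown",
          "N I", "N I", "N I", "N I", "N I", "N I", "Unknown",
          "N I", "O I", "N I", "N I")
  data.frame(index = seq_along(wl), wavelength_nm = wl, species = sp,
             stringsAsFactors = FALSE)
}

#' Element group of each emission line
#'
#' Collapses the species label to its emitting element (or molecular band):
#' `"Mg II"` and `"Mg I"` both map to `"Mg"`, all CN band heads to `"CN"`,
#' the hydrogen Balmer line to `"H"`, and unidentified lines to `"Unknown"`.
#'
#' @param lines A line library as returned by [libs_line_library()].
#' @return Character vector of group labels, one per line.
#' @export
line_element <- function(lines = libs_line_library()) {
  sp <- lines$species
  out <- vapply(strsplit(sp, " ", fixed = TRUE), `[[`, "", 1L)
  out[startsWith(sp, "H\u03b1")] <- "H"
  out
}

## column labels used in peak-table CSV headers: "<wavelength>_<species>"
line_labels <- function(lines = libs_line_library()) {
  paste0(sprintf("%.2f", lines$wavelength_nm), "_",
         gsub(" ", "_", lines$species, fixed = TRUE))
}

#' Read / write a line library as CSV
#'
#' The on-disk dialect is a comma-separated UTF-8 file with mandatory header
#' `index,wavelength_nm,species`.
#'
#' @param path File path.
#' @param lines A line library data.frame.
#' @return `read_line_library_csv()` returns the validated library
#'   data.frame; `write_line_library_csv()` returns `path` invisibly.
#' @export
read_line_library_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = "species"))
  need <- c("index", "wavelength_nm", "species")
  if (!identical(names(dt), need))
    stop_("line library must have columns %s, got: %s",
          paste(need, collapse = ","), paste(names(dt), collapse = ","))
  validate_line_library(dt)
  dt
}

#' @rdname read_line_library_csv
#' @export
write_line_library_csv <- function(lines, path) {
  validate_line_library(lines)
  data.table::fwrite(lines, path, bom = FALSE)
  invisible(path)
}

validate_line_library <- function(lines) {
  if (nrow(lines) != 43L)
    stop_("line library must have exactly 43 entries, got %d", nrow(lines))
  wl <- lines$wavelength_nm
  if (any(diff(wl) <= 0))
    stop_("line wavelengths must be strictly ascending (violated at row %d)",
          which(diff(wl) <= 0)[1L] + 1L)
  if (any(wl < 240 | wl > 860))
    stop_("line wavelengths must lie within [240, 860] nm")
  invisible(lines)
}
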