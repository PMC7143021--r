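#' Read / write spectra as a wide CSV table
#'
#' The on-disk dialect is comma-separated UTF-8 with a mandatory header:
#' first column `sample_id`, second `fraction`, remaining columns one per
#' grid wavelength (header is the wavelength in nm, 2 decimals).  The
#' header wavelengths must parse as a strictly ascending numeric grid, rows
#' must be complete and numeric, and all spectra written to one file must
#' share a single grid.  Values are written at full double precision, so a
#' write/read round trip reproduces intensities to better than 1e-12
#' relative.
#'
#' @param path File path.
#' @param spectra List of `libs_spectrum` objects on a common grid.
#' @return `read_spectra_csv()` returns a list of `libs_spectrum`;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (nrow(dt) == 0L) stop_("no samples in '%s'", path)
  if (ncol(dt) < 3L || names(dt)[1L] != "sample_id" ||
      names(dt)[2L] != "fraction")
    stop_("expected columns sample_id, fraction, <wavelengths...> in '%s'",
          path)
  wl <- suppressWarnings(as.numeric(names(dt)[-(1:2)]))
  if (anyNA(wl))
    stop_("non-numeric wavelength column header '%s' (column %d)",
          names(dt)[-(1:2)][which(is.na(wl))[1L]], which(is.na(wl))[1L] + 2L)
  if (any(diff(wl) <= 0)) {
    bad <- which(diff(wl) <= 0)[1L] + 1L
    stop_("wavelength header out of order at column %d ('%s')",
          bad + 2L, names(dt)[-(1:2)][bad])
  }
  mat <- as.matrix(dt[, -(1:2), drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2L, as.numeric))),
                 arr.ind = TRUE)
    stop_("non-numeric or missing intensity at row %d, column '%s'",
          bad[1L, 1L], colnames(mat)[bad[1L, 2L]])
  }
  frac <- suppressWarnings(as.numeric(dt$fraction))
  lapply(seq_len(nrow(dt)), function(i)
    libs_spectrum(wl, mat[i, ], sample_id = dt$sample_id[i],
                  fraction = frac[i]))
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  if (length(spectra) == 0L) stop_("no spectra to write")
  stopifnot(all(vapply(spectra, inherits, TRUE, "libs_spectrum")))
  grid <- spectra[[1L]]$grid_nm
  for (s in spectra)
    if (!isTRUE(all.equal(s$grid_nm, grid)))
      stop_("all spectra must share one wavelength grid")
  mat <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  dt <- data.table::data.table(
    sample_id = vapply(spectra, `[[`, "", "sample_id"),
    fraction = fmt17(vapply(spectra, `[[`, 0.0, "fraction")))
  inten <- data.table::as.data.table(matrix(fmt17(mat), nrow = nrow(mat)))
  data.table::setnames(inten, sprintf("%.2f", grid))
  data.table::fwrite(cbind(dt, inten), path, bom = FALSE, quote = FALSE)
  invisible(path)
}

## lossless, deterministic decimal rendering of doubles (17 significant
## digits round-trips every IEEE double exactly)
fmt17 <- function(x) sprintf("%.17g", x)

#' Read / write a peak-intensity table as CSV
#'
#' Columns: `sample_id`, `fraction`, then one column per emission line
#' labelled `<wavelength>_<species>` (e.g. `279.58_Mg_II`), in library
#' order.  The reader validates the column set against the supplied line
#' library.
#'
#' @param path File path.
#' @param table A `peak_table` (see [build_peak_table()]).
#' @param lines Line library against which columns are validated.
#' @return `read_peak_table_csv()` returns a `peak_table`;
#'   `write_peak_table_csv()` returns `path` invisibly.
#' @export
read_peak_table_csv <- function(path, lines = libs_line_library()) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (nrow(dt) == 0L) stop_("no samples in '%s'", path)
  if (names(dt)[1L] != "sample_id")
    stop_("first column must be sample_id")
  if (length(names(dt)) < 2L || names(dt)[2L] != "fraction")
    stop_("peak table is missing the fraction column")
  labs <- line_labels(lines)
  got <- names(dt)[-(1:2)]
  if (length(got) != length(labs))
    stop_("dimension mismatch: table has %d line columns, library has %d",
          length(got), length(labs))
  if (!identical(got, labs))
    stop_("line columns do not match library (first difference: '%s' vs '%s')",
          got[which(got != labs)[1L]], labs[which(got != labs)[1L]])
  mat <- as.matrix(dt[, -(1:2), drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat))
    stop_("peak table contains non-numeric or missing intensities")
  peak_table(sample_ids = dt$sample_id,
             fractions = as.numeric(dt$fraction),
             intensities = mat, lines = lines)
}

#' @rdname read_peak_table_csv
#' @export
write_peak_table_csv <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  dt <- data.table::data.table(sample_id = table$sample_ids,
                               fraction = fmt17(table$fractions))
  inten <- data.table::as.data.table(
    matrix(fmt17(table$intensities), nrow = nrow(table$intensities)))
  data.table::setnames(inten, line_labels(table$lines))
  data.table::fwrite(cbind(dt, inten), path, bom = FALSE, quote = FALSE)
  invisible(path)
}

#' Write evaluation reports as JSON
#'
#' Serializes one or more evaluation reports (see [refit_selected()] and
#' [run_study()]) to a single JSON document: method, adulterant, number of
#' latent variables and of variables, r/RMSE for the calibration,
#' cross-validation and prediction sets, and per-sample actual/predicted
#' pairs for scatter plotting.
#'
#' @param reports One `evaluation_report` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    r <- unclass(r)
    attributes(r) <- list(names = names(r))  # drop fitted-model attributes
    r
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a selection result as CSV
#'
#' One row per library line: wavelength, species, importance score and
#' whether the line was selected — the tabular equivalent of a
#' selection-mask heat map.
#'
#' @param selection A `selection_result`.
#' @param lines Line library the scores refer to.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(selection, lines, path) {
  stopifnot(inherits(selection, "selection_result"))
  dt <- data.table::data.table(
    index = lines$index,
    wavelength_nm = lines$wavelength_nm,
    species = lines$species,
    method = selection$method,
    score = as.numeric(selection$scores),
    selected = as.logical(selection$mask))
  data.table::fwrite(dt, path, bom = FALSE)
  invisible(path)
}
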