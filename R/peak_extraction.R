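#' Observed peak intensity of one emission line
#'
#' The variable used throughout the pipeline is the observed (raw) peak
#' intensity: the maximum intensity over all grid points within
#' `+/- half_window_nm` of the line's nominal wavelength.  No baseline
#' subtraction or line fitting is applied.
#'
#' @param spectrum A `libs_spectrum`.
#' @param line One-row slice of the line library (or a list with
#'   `wavelength_nm`).
#' @param half_window_nm Half-width of the search window (nm).  The default
#'   0.25 nm separates the Na doublet (0.61 nm apart) while tolerating a
#'   couple of grid steps of line-position mismatch.
#' @return Non-negative scalar intensity.
#' @export
peak_intensity <- function(spectrum, line, half_window_nm = 0.25) {
  stopifnot(inherits(spectrum, "libs_spectrum"))
  wl <- if (is.numeric(line)) line else line$wavelength_nm
  stopifnot(length(wl) == 1L, is.finite(wl))
  if (half_window_nm <= 0) stop_("half_window_nm must be positive")
  if (wl < min(spectrum$grid_nm) || wl > max(spectrum$grid_nm))
    stop_("line at %.2f nm lies outside the spectrum grid", wl)
  sel <- spectrum$grid_nm >= wl - half_window_nm &
    spectrum$grid_nm <= wl + half_window_nm
  if (!any(sel))
    stop_("no grid points within %.3g nm of line at %.2f nm",
          half_window_nm, wl)
  max(spectrum$intensity[sel])
}

#' Peak-table container
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param fractions Numeric adulterant fractions aligned with the rows.
#' @param intensities n_samples x n_lines non-negative matrix.
#' @param lines The emission-line library the columns refer to.
#' @return Object of class `peak_table`.
#' @export
peak_table <- function(sample_ids, fractions, intensities, lines) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(sample_ids) ||
      nrow(intensities) != length(fractions))
    stop_("row count (%d) must match sample_ids (%d) and fractions (%d)",
          nrow(intensities), length(sample_ids), length(fractions))
  if (ncol(intensities) != nrow(lines))
    stop_("column count (%d) must match line library size (%d)",
          ncol(intensities), nrow(lines))
  if (anyNA(intensities)) stop_("peak table must not contain missing values")
  dimnames(intensities) <- list(sample_ids, line_labels(lines))
  structure(list(sample_ids = as.character(sample_ids),
                 fractions = as.numeric(fractions),
                 intensities = intensities, lines = lines),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d samples x %d lines\n",
              nrow(x$intensities), ncol(x$intensities)))
  invisible(x)
}

#' Build the samples-by-lines peak-intensity table
#'
#' Extracts [peak_intensity()] for every line of the library from every
#' spectrum, preserving input order; the adulterant fractions are copied
#' from the spectra.
#'
#' @param spectra List of `libs_spectrum` on one common grid.
#' @param lines Line library.
#' @param half_window_nm Search half-window, see [peak_intensity()].
#' @return A `peak_table` of dimension `length(spectra)` x `nrow(lines)`.
#' @export
build_peak_table <- function(spectra, lines = libs_line_library(),
                             half_window_nm = 0.25) {
  if (length(spectra) == 0L) stop_("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, TRUE, "libs_spectrum")))
  grid <- spectra[[1L]]$grid_nm
  for (s in spectra)
    if (!isTRUE(all.equal(s$grid_nm, grid)))
      stop_("all spectra must share one wavelength grid")
  ## precompute window indices once: all spectra share the grid
  windows <- lapply(lines$wavelength_nm, function(wl) {
    if (wl < min(grid) || wl > max(grid))
      stop_("line at %.2f nm lies outside the spectrum grid", wl)
    idx <- which(grid >= wl - half_window_nm & grid <= wl + half_window_nm)
    if (length(idx) == 0L)
      stop_("no grid points within %.3g nm of line at %.2f nm",
            half_window_nm, wl)
    idx
  })
  mat <- matrix(0, nrow = length(spectra), ncol = nrow(lines))
  for (i in seq_along(spectra)) {
    y <- spectra[[i]]$intensity
    mat[i, ] <- vapply(windows, function(idx) max(y[idx]), 0.0)
  }
  peak_table(sample_ids = vapply(spectra, `[[`, "", "sample_id"),
             fractions = vapply(spectra, `[[`, 0.0, "fraction"),
             intensities = mat, lines = lines)
}

## subset a peak table's variables by logical mask or index
subset_peak_table <- function(table, keep) {
  stopifnot(inherits(table, "peak_table"))
  idx <- if (is.logical(keep)) which(keep) else keep
  if (length(idx) == 0L) stop_("variable subset must be non-empty")
  lines <- table$lines[idx, , drop = FALSE]
  structure(list(sample_ids = table$sample_ids, fractions = table$fractions,
                 intensities = table$intensities[, idx, drop = FALSE],
                 lines = lines),
            class = "peak_table")
}
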