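#' Construct a spectrum object
#'
#' @param grid_nm Ascending wavelength grid (nm).
#' @param intensity Non-negative intensity vector, same length as `grid_nm`.
#' @param sample_id Sample identifier.
#' @param fraction Adulterant fraction in `[0, 1]`, or `NA` when unknown.
#' @return Object of class `libs_spectrum`.
#' @export
libs_spectrum <- function(grid_nm, intensity, sample_id = "sample",
                          fraction = NA_real_) {
  if (length(grid_nm) != length(intensity))
    stop_("grid and intensity lengths differ (%d vs %d)",
          length(grid_nm), length(intensity))
  if (any(diff(grid_nm) <= 0))
    stop_("wavelength grid must be strictly ascending")
  structure(list(grid_nm = as.numeric(grid_nm),
                 intensity = as.numeric(intensity),
                 sample_id = as.character(sample_id),
                 fraction = as.numeric(fraction)),
            class = "libs_spectrum")
}

#' @export
print.libs_spectrum <- function(x, ...) {
  cat(sprintf("<libs_spectrum> %s: %d points, %.2f-%.2f nm, fraction = %s\n",
              x$sample_id, length(x$grid_nm), min(x$grid_nm), max(x$grid_nm),
              ifelse(is.na(x$fraction), "NA", format(x$fraction))))
  invisible(x)
}

#' Render a noiseless spectrum from an amplitude profile
#'
#' Realizes each emission line as a Gaussian peak of height equal to its
#' profile amplitude, centred at the line's nominal wavelength, on a uniform
#' wavelength grid, on top of a constant baseline.  The default full width
#' at half maximum of 0.30 nm is narrow enough to resolve the Na doublet at
#' 589.03/589.64 nm; the default 0.05 nm grid step resolves every pair of
#' library lines.
#'
#' @param profile An `endmember_profile`.
#' @param grid_step_nm Grid spacing (nm); must satisfy
#'   `grid_step_nm <= peak_fwhm_nm / 2` so peaks stay resolvable.
#' @param peak_fwhm_nm Peak full width at half maximum (nm).
#' @param baseline Constant baseline level (intensity units).
#' @param range_nm Two-element wavelength range of the grid.
#' @param sample_id,fraction Passed through to the spectrum object.
#' @return A `libs_spectrum`.
#' @export
render_spectrum <- function(profile, grid_step_nm = 0.05,
                            peak_fwhm_nm = 0.30, baseline = 1,
                            range_nm = c(240, 860),
                            sample_id = profile$kind, fraction = NA_real_) {
  stopifnot(inherits(profile, "endmember_profile"))
  if (!is.numeric(grid_step_nm) || grid_step_nm <= 0)
    stop_("grid_step_nm must be positive")
  if (!is.numeric(peak_fwhm_nm) || peak_fwhm_nm <= 0)
    stop_("peak_fwhm_nm must be positive")
  if (grid_step_nm > peak_fwhm_nm / 2)
    stop_("grid step %.3g nm too coarse for FWHM %.3g nm (need step <= FWHM/2)",
          grid_step_nm, peak_fwhm_nm)
  grid <- seq(range_nm[1L], range_nm[2L], by = grid_step_nm)
  y <- rep(as.numeric(baseline), length(grid))
  sigma <- peak_fwhm_nm / (2 * sqrt(2 * log(2)))
  halfspan <- 6 * sigma   # Gaussian support truncated at 6 sigma (< 2e-8 rel.)
  wl <- profile$lines$wavelength_nm
  amp <- profile$amplitudes
  for (j in seq_along(wl)) {
    if (amp[j] == 0) next
    lo <- max(1L, ceiling((wl[j] - halfspan - range_nm[1L]) / grid_step_nm) + 1L)
    hi <- min(length(grid),
              floor((wl[j] + halfspan - range_nm[1L]) / grid_step_nm) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] + amp[j] * exp(-((grid[idx] - wl[j])^2) / (2 * sigma^2))
  }
  libs_spectrum(grid, y, sample_id = sample_id, fraction = fraction)
}

#' Shot-noise configuration
#'
#' Parameters of the measurement emulation: each laser shot adds independent
#' zero-mean Gaussian noise of standard deviation `sigma_shot` at every
#' pixel, and `n_shots` shots are averaged (the instrument collects 100
#' successive spectra per sample and averages them to suppress sample
#' inhomogeneity).
#'
#' @param sigma_shot Per-shot additive noise SD (intensity units; >= 0).
#' @param n_shots Number of averaged shots (>= 1, default 100).
#' @param baseline_level Constant spectral baseline used at render time.
#' @param seed Integer seed, or `NULL` to consume the session RNG stream.
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(sigma_shot = 5, n_shots = 100L, baseline_level = 1,
                         seed = NULL) {
  if (!is.numeric(sigma_shot) || sigma_shot < 0)
    stop_("sigma_shot must be >= 0")
  if (!is_count(n_shots)) stop_("n_shots must be a positive integer")
  if (!is.numeric(baseline_level) || baseline_level < 0)
    stop_("baseline_level must be >= 0")
  structure(list(sigma_shot = sigma_shot, n_shots = as.integer(n_shots),
                 baseline_level = baseline_level, seed = seed),
            class = "noise_config")
}

#' Simulate a shot-averaged measurement of a spectrum
#'
#' Adds independent N(0, `sigma_shot`) noise to every pixel of each of
#' `n_shots` copies of the input spectrum, averages the copies, and clips
#' negative averaged intensities to zero (physical non-negativity; clipping
#' is applied after averaging).  The averaged pixel noise has standard
#' deviation `sigma_shot / sqrt(n_shots)` before clipping.
#'
#' @param spectrum A `libs_spectrum`.
#' @param noise A `noise_config`; with `sigma_shot = 0` the input is
#'   returned unchanged.
#' @return A `libs_spectrum` with the same grid.
#' @export
simulate_measurement <- function(spectrum, noise = noise_config()) {
  stopifnot(inherits(spectrum, "libs_spectrum"),
            inherits(noise, "noise_config"))
  if (noise$sigma_shot == 0) return(spectrum)
  npx <- length(spectrum$intensity)
  draw <- function() {
    shots <- matrix(rnorm(npx * noise$n_shots, 0, noise$sigma_shot),
                    nrow = npx, ncol = noise$n_shots)
    spectrum$intensity + rowMeans(shots)
  }
  avg <- if (is.null(noise$seed)) draw() else
    withr::with_seed(fold_seed(noise$seed), draw())
  spectrum$intensity <- pmax(avg, 0)
  spectrum
}

#' Binary-mixture design
#'
#' The calibration series covers 21 adulteration levels from 0 to 100\% in
#' 5\% steps; the external prediction series covers 13 levels from 0 to 96\%
#' in 8\% steps.  With the default 3 replicates this yields 63 calibration
#' and 39 prediction samples.
#'
#' @param calibration_levels Fractions in `[0, 1]` for the calibration set.
#' @param prediction_levels Fractions in `[0, 1]` for the prediction set.
#' @param replicates Replicate mixtures per level (default 3).
#' @return Object of class `mixture_design`.
#' @export
mixture_design <- function(calibration_levels = seq(0, 1, by = 0.05),
                           prediction_levels = seq(0, 0.96, by = 0.08),
                           replicates = 3L) {
  for (lv in list(calibration_levels, prediction_levels))
    if (length(lv) > 0 && (any(lv < 0) || any(lv > 1)))
      stop_("design fractions must lie in [0, 1]")
  if (!is_count(replicates)) stop_("replicates must be a positive integer")
  structure(list(calibration_levels = calibration_levels,
                 prediction_levels = prediction_levels,
                 replicates = as.integer(replicates)),
            class = "mixture_design")
}

#' Generate a calibration + prediction spectral dataset
#'
#' Draws one amplitude profile per endmember (shared background lines, see
#' [make_endmember_profile()]), mixes them linearly at every design level,
#' renders each mixture and simulates independent shot-averaged replicate
#' measurements.  All randomness derives from `seed` through a fixed
#' counter scheme, so results are reproducible and adding consumers does not
#' shift existing draws.
#'
#' @param pure_kind,adulterant_kind Distinct endmember kinds; the pure
#'   component carries fraction 0 and the adulterant fraction 1.
#' @param design A [mixture_design()].
#' @param noise A [noise_config()]; its `seed` field is ignored here (child
#'   seeds come from `seed`).
#' @param seed Master integer seed.
#' @param config Endmember amplitude configuration.
#' @param grid_step_nm,peak_fwhm_nm Rendering parameters, see
#'   [render_spectrum()].
#' @return A list with class `libs_dataset`: `calibration` and `prediction`
#'   (lists of `libs_spectrum`, each carrying its true fraction), `lines`,
#'   and the generating `design`, `noise`, `seed`.
#' @export
generate_dataset <- function(pure_kind, adulterant_kind,
                             design = mixture_design(),
                             noise = noise_config(), seed = 1L,
                             config = endmember_config(),
                             grid_step_nm = 0.05, peak_fwhm_nm = 0.30) {
  if (identical(pure_kind, adulterant_kind))
    stop_("pure and adulterant kinds must be distinct")
  if (length(design$calibration_levels) == 0L ||
      length(design$prediction_levels) == 0L)
    stop_("design level lists must be non-empty")
  pure <- make_endmember_profile(pure_kind, seed = seed, config = config)
  adu <- make_endmember_profile(adulterant_kind, seed = seed, config = config)
  generate_from_profiles(pure, adu, design = design, noise = noise,
                         seed = seed, grid_step_nm = grid_step_nm,
                         peak_fwhm_nm = peak_fwhm_nm)
}

#' @rdname generate_dataset
#' @param pure,adulterant Pre-built `endmember_profile` objects (allows
#'   custom contrasts, e.g. designated informative lines).
#' @export
generate_from_profiles <- function(pure, adulterant,
                                   design = mixture_design(),
                                   noise = noise_config(), seed = 1L,
                                   grid_step_nm = 0.05,
                                   peak_fwhm_nm = 0.30) {
  stopifnot(inherits(design, "mixture_design"),
            inherits(noise, "noise_config"))
  if (length(design$calibration_levels) == 0L ||
      length(design$prediction_levels) == 0L)
    stop_("design level lists must be non-empty")
  make_set <- function(levels, reps, set_name, seed_base) {
    out <- vector("list", length(levels) * reps)
    k <- 0L
    for (i in seq_along(levels)) {
      mixed <- mix_profiles(pure, adulterant, levels[i])
      clean <- render_spectrum(mixed, grid_step_nm = grid_step_nm,
                               peak_fwhm_nm = peak_fwhm_nm,
                               baseline = noise$baseline_level,
                               fraction = levels[i])
      for (r in seq_len(reps)) {
        k <- k + 1L
        clean$sample_id <- sprintf("%s_L%02d_r%d", set_name, i, r)
        shot <- noise
        shot$seed <- child_seed(seed, seed_base + k)
        out[[k]] <- simulate_measurement(clean, shot)
      }
    }
    out
  }
  cal <- make_set(design$calibration_levels, design$replicates, "cal", 1000L)
  pred <- make_set(design$prediction_levels, design$replicates, "pred", 5000L)
  structure(list(calibration = cal, prediction = pred, lines = pure$lines,
                 design = design, noise = noise, seed = seed),
            class = "libs_dataset")
}
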