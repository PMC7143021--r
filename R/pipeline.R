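#' Univariate screen over the emission-line library
#'
#' Regresses the adulterant fraction on each line's peak intensity in turn
#' and tabulates the correlation coefficient (reported unsigned, the
#' conventional presentation) and the RMSE of each single-line model.
#' Constant columns (possible in noiseless simulations) are flagged rather
#' than fatal.
#'
#' @param peaks A `peak_table`.
#' @return A data.frame with one row per line, ordered by wavelength:
#'   `index`, `wavelength_nm`, `species`, `r` (unsigned), `rmse` (fraction
#'   units), `constant` (logical flag).
#' @export
run_univariate_screen <- function(peaks) {
  stopifnot(inherits(peaks, "peak_table"))
  lines <- peaks$lines
  n <- nrow(lines)
  r <- rmse_v <- rep(NA_real_, n)
  const <- rep(FALSE, n)
  usable <- nonconstant_cols(peaks$intensities)
  for (j in seq_len(n)) {
    x <- peaks$intensities[, j]
    if (!usable[j]) { const[j] <- TRUE; next }
    fit <- ols_univariate(x, peaks$fractions)
    r[j] <- abs(fit$r)
    rmse_v[j] <- fit$rmse
  }
  data.frame(index = lines$index, wavelength_nm = lines$wavelength_nm,
             species = lines$species, r = r, rmse = rmse_v,
             constant = const, stringsAsFactors = FALSE)
}

#' Study configuration
#'
#' Bundles every tunable of the full study: which endmember is the pure
#' component, which adulterants are quantified against it, the mixing
#' design, the noise model, rendering and peak-extraction parameters, the
#' cross-validation settings and the GA hyperparameters.
#'
#' @param pure Pure-component endmember kind (default `"acacia"`).
#' @param adulterants Character vector of adulterant kinds.
#' @param design A [mixture_design()].
#' @param noise A [noise_config()].
#' @param endmembers An [endmember_config()].
#' @param grid_step_nm,peak_fwhm_nm Rendering parameters.
#' @param half_window_nm Peak-extraction half window.
#' @param A_max,cv_folds Cross-validation settings.
#' @param ga A [ga_config()] (its seed is overridden by the study seed).
#' @return Object of class `study_config`.
#' @export
study_config <- function(pure = "acacia",
                         adulterants = c("hfcs55", "hfcs90", "rape"),
                         design = mixture_design(),
                         noise = noise_config(),
                         endmembers = endmember_config(),
                         grid_step_nm = 0.05, peak_fwhm_nm = 0.30,
                         half_window_nm = 0.25,
                         A_max = 10L, cv_folds = 10L,
                         ga = ga_config()) {
  stopifnot(length(adulterants) >= 1L, !pure %in% adulterants)
  structure(list(pure = pure, adulterants = adulterants, design = design,
                 noise = noise, endmembers = endmembers,
                 grid_step_nm = grid_step_nm, peak_fwhm_nm = peak_fwhm_nm,
                 half_window_nm = half_window_nm, A_max = as.integer(A_max),
                 cv_folds = as.integer(cv_folds), ga = ga),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Flat YAML keys override the corresponding [study_config()] defaults.
#' Recognized keys: `pure`, `adulterants`, `calibration_levels`,
#' `prediction_levels`, `replicates`, `sigma_shot`, `n_shots`,
#' `baseline_level`, `jitter`, `grid_step_nm`, `peak_fwhm_nm`,
#' `half_window_nm`, `A_max`, `cv_folds`, and a `ga` block with
#' [ga_config()] fields.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- mixture_design(
    calibration_levels = y$calibration_levels %||% seq(0, 1, by = 0.05),
    prediction_levels = y$prediction_levels %||% seq(0, 0.96, by = 0.08),
    replicates = y$replicates %||% 3L)
  noise <- noise_config(sigma_shot = y$sigma_shot %||% 5,
                        n_shots = y$n_shots %||% 100L,
                        baseline_level = y$baseline_level %||% 1)
  ga <- do.call(ga_config, y$ga %||% list())
  study_config(pure = y$pure %||% "acacia",
               adulterants = y$adulterants %||%
                 c("hfcs55", "hfcs90", "rape"),
               design = design, noise = noise,
               endmembers = endmember_config(jitter = y$jitter %||% 0.1),
               grid_step_nm = y$grid_step_nm %||% 0.05,
               peak_fwhm_nm = y$peak_fwhm_nm %||% 0.30,
               half_window_nm = y$half_window_nm %||% 0.25,
               A_max = y$A_max %||% 10L, cv_folds = y$cv_folds %||% 10L,
               ga = ga)
}

#' Run the full adulteration study
#'
#' For every adulterant in the configuration: generate the calibration and
#' prediction spectra, extract the 43-line peak table, run the univariate
#' screen, fit the all-variable PLSR, and fit the three reduced models
#' (GA-, VIP- and SR-PLSR, the latter two scored on the full model at its
#' CV-chosen factor count and re-cross-validated after subsetting).  All
#' randomness is derived from `seed` through a fixed counter scheme
#' (100 seeds reserved per adulterant branch), so runs are reproducible and
#' branches are independent.  A failure in one adulterant branch is caught
#' and logged; the other branches still run.
#'
#' @param config A [study_config()].
#' @param seed Master integer seed.
#' @return Object of class `study_result`: lists `reports`
#'   (`evaluation_report`s keyed `<adulterant>.<method>`), `univariate`
#'   (screen data.frames per adulterant), `selections` (selection results
#'   keyed `<adulterant>.<method>`), `peak_tables`, `errors`, and `seed`.
#' @export
run_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  reports <- list(); univ <- list(); selections <- list()
  tables <- list(); errors <- list()
  for (j in seq_along(config$adulterants)) {
    adu <- config$adulterants[j]
    branch <- tryCatch(
      run_adulterant_branch(config, adu, child_seed(seed, 100L * j)),
      error = function(e) e)
    if (inherits(branch, "error")) {
      errors[[adu]] <- conditionMessage(branch)
      message(sprintf("branch '%s' failed: %s", adu, errors[[adu]]))
      next
    }
    univ[[adu]] <- branch$univariate
    tables[[adu]] <- branch$tables
    for (m in names(branch$reports))
      reports[[paste(adu, m, sep = ".")]] <- branch$reports[[m]]
    for (m in names(branch$selections))
      selections[[paste(adu, m, sep = ".")]] <- branch$selections[[m]]
  }
  structure(list(reports = reports, univariate = univ,
                 selections = selections, peak_tables = tables,
                 errors = errors, seed = seed),
            class = "study_result")
}

## one adulterant branch: simulate, extract, screen, model.  Child-seed
## counters: +0 dataset, +1 full-model CV folds, +2 GA, +3..+5 reduced CVs.
run_adulterant_branch <- function(config, adulterant, seed) {
  ds <- generate_dataset(config$pure, adulterant, design = config$design,
                         noise = config$noise, seed = child_seed(seed, 0L),
                         config = config$endmembers,
                         grid_step_nm = config$grid_step_nm,
                         peak_fwhm_nm = config$peak_fwhm_nm)
  peaks_cal <- build_peak_table(ds$calibration, ds$lines,
                                half_window_nm = config$half_window_nm)
  peaks_pred <- build_peak_table(ds$prediction, ds$lines,
                                 half_window_nm = config$half_window_nm)
  screen <- run_univariate_screen(peaks_cal)

  full <- evaluate_pls(peaks_cal, peaks_pred, method = "PLSR",
                       adulterant = adulterant, A_max = config$A_max,
                       cv_folds = config$cv_folds,
                       seed = child_seed(seed, 1L))
  model <- attr(full, "model")
  kept <- attr(full, "kept")
  p_all <- ncol(peaks_cal$intensities)

  ## VIP / SR are scored on the full-variable model at its CV-chosen LV
  ## count; masks are re-expanded to the 43-line library (dropped constant
  ## columns score NA / unselected)
  expand <- function(sel) {
    scores <- rep(NA_real_, p_all); mask <- rep(FALSE, p_all)
    scores[kept] <- sel$scores; mask[kept] <- sel$mask
    names(scores) <- colnames(peaks_cal$intensities)
    out <- selection_result(sel$method, scores, sel$threshold, mask)
    attributes(out) <- c(attributes(out),
                         attributes(sel)[c("elite_fitness",
                                           "best_chromosomes")])
    out
  }
  vip <- expand(vip_select(model))
  sr <- expand(sr_select(model, peaks_cal$intensities[, kept, drop = FALSE],
                         n_cal = length(peaks_cal$fractions)))
  ga_cfg <- config$ga
  ga_cfg$seed <- child_seed(seed, 2L)
  ga <- expand(ga_select(peaks_cal$intensities[, kept, drop = FALSE],
                         peaks_cal$fractions, ga_cfg))

  sels <- list(`GA` = ga, `VIP` = vip, `SR` = sr)
  reports <- list(PLSR = full)
  for (i in seq_along(sels)) {
    m <- names(sels)[i]
    reports[[paste0(m, "-PLSR")]] <-
      refit_selected(peaks_cal, peaks_pred, sels[[i]],
                     cv_seed = child_seed(seed, 2L + i),
                     adulterant = adulterant, A_max = config$A_max,
                     cv_folds = config$cv_folds)
  }
  list(reports = reports, selections = sels, univariate = screen,
       tables = list(calibration = peaks_cal, prediction = peaks_pred))
}

#' Render a study's reports as a Table-2-style data.frame
#'
#' @param study A `study_result`.
#' @return data.frame with one row per adulterant/method combination;
#'   RMSE columns are percentages with one decimal.
#' @export
study_summary <- function(study) {
  stopifnot(inherits(study, "study_result"))
  rows <- lapply(study$reports, function(rep) {
    data.frame(adulterant = rep$adulterant, method = rep$method,
               n_LV = rep$n_LV, n_vars = rep$n_vars,
               r_cal = round(rep$r_cal, 3),
               rmse_cal = sprintf("%.1f%%", 100 * rep$rmse_cal),
               r_cv = round(rep$r_cv, 3),
               rmse_cv = sprintf("%.1f%%", 100 * rep$rmse_cv),
               r_pred = round(rep$r_pred, 3),
               rmse_pred = sprintf("%.1f%%", 100 * rep$rmse_pred),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all study artifacts to a directory
#'
#' Emits `univariate_<adulterant>.csv`, `selection_<method>_<adulterant>.csv`,
#' per-set predicted-vs-actual CSVs, and a combined `report.json`.
#'
#' @param study A `study_result`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "study_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (adu in names(study$univariate)) {
    u <- study$univariate[[adu]]
    u$rmse_pct <- sprintf("%.1f%%", 100 * u$rmse)
    data.table::fwrite(u, file.path(outdir,
                                    sprintf("univariate_%s.csv", adu)))
  }
  for (key in names(study$selections)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    lines <- study$peak_tables[[parts[1L]]]$calibration$lines
    write_selection_csv(study$selections[[key]], lines,
                        file.path(outdir, sprintf("selection_%s_%s.csv",
                                                  tolower(parts[2L]),
                                                  parts[1L])))
  }
  for (key in names(study$reports)) {
    rep <- study$reports[[key]]
    for (set in names(rep$predictions))
      data.table::fwrite(rep$predictions[[set]],
                         file.path(outdir, sprintf("predicted_%s_%s.csv",
                                                   gsub("\\W", "_", key),
                                                   set)))
  }
  write_report_json(study$reports, file.path(outdir, "report.json"))
  invisible(outdir)
}
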