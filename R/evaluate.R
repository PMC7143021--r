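#' Fit, cross-validate and evaluate a PLSR model on peak tables
#'
#' The workhorse behind every report row: optionally subsets the variables,
#' drops zero-variance columns (with a message), chooses the latent-variable
#' count by seeded 10-fold cross-validation, fits the final SIMPLS model on
#' the full calibration set, and evaluates r and RMSE on the calibration
#' set, the cross-validation (held-out predictions at the chosen factor
#' count) and the external prediction set.
#'
#' @param peaks_cal,peaks_pred Calibration and prediction `peak_table`s on
#'   the same line library.
#' @param mask Optional logical mask over the library's variables.
#' @param method Report label, e.g. `"PLSR"` or `"VIP-PLSR"`.
#' @param adulterant Label recorded in the report.
#' @param A_max,cv_folds Cross-validation settings.
#' @param seed Seed for the CV fold assignment.
#' @return Object of class `evaluation_report`: `adulterant`, `method`,
#'   `n_LV`, `n_vars`, `r_cal`, `rmse_cal`, `r_cv`, `rmse_cv`, `r_pred`,
#'   `rmse_pred`, and `predictions` (per-sample actual/predicted pairs for
#'   both sets).  The fitted `pls_model` is attached as attribute `model`,
#'   the kept-variable indices as attribute `kept`.
#' @export
evaluate_pls <- function(peaks_cal, peaks_pred, mask = NULL,
                         method = "PLSR", adulterant = "adulterant",
                         A_max = 10L, cv_folds = 10L, seed = 1L) {
  stopifnot(inherits(peaks_cal, "peak_table"),
            inherits(peaks_pred, "peak_table"))
  if (!identical(line_labels(peaks_cal$lines), line_labels(peaks_pred$lines)))
    stop_("calibration and prediction tables use different line libraries")
  p_all <- ncol(peaks_cal$intensities)
  keep <- if (is.null(mask)) rep(TRUE, p_all) else as.logical(mask)
  if (length(keep) != p_all)
    stop_("mask length %d does not match %d variables", length(keep), p_all)
  if (!any(keep)) stop_("selection mask is empty")
  ## zero-variance columns cannot be autoscaled; exclude them up front
  usable <- nonconstant_cols(peaks_cal$intensities)
  dropped <- keep & !usable
  if (any(dropped))
    message(sprintf("dropping %d zero-variance variable(s): %s",
                    sum(dropped),
                    paste(head(colnames(peaks_cal$intensities)[dropped], 5L),
                          collapse = ", ")))
  keep <- keep & usable
  if (!any(keep)) stop_("no usable (non-constant) variables left")

  X_cal <- peaks_cal$intensities[, keep, drop = FALSE]
  X_pred <- peaks_pred$intensities[, keep, drop = FALSE]
  y_cal <- peaks_cal$fractions
  y_pred <- peaks_pred$fractions

  cv <- kfold_cv(X_cal, y_cal, A_max = A_max, k = cv_folds, seed = seed)
  A <- cv$chosen_A
  model <- simpls_fit(X_cal, y_cal, A)

  ## held-out CV predictions at the chosen A (refit per fold, no leakage)
  cv_pred <- rep(NA_real_, length(y_cal))
  for (f in sort(unique(cv$fold_assignments))) {
    tr <- cv$fold_assignments != f
    m <- simpls_fit(X_cal[tr, , drop = FALSE], y_cal[tr],
                    min(A, sum(tr) - 1L, ncol(X_cal)))
    cv_pred[!tr] <- pls_predict(m, X_cal[!tr, , drop = FALSE],
                                A = min(A, m$A))
  }
  fit_cal <- model$fitted
  fit_pred <- pls_predict(model, X_pred)

  structure(list(
    adulterant = adulterant, method = method,
    n_LV = A, n_vars = sum(keep),
    r_cal = pearson_r(fit_cal, y_cal), rmse_cal = rmse(fit_cal, y_cal),
    r_cv = pearson_r(cv_pred, y_cal), rmse_cv = rmse(cv_pred, y_cal),
    r_pred = pearson_r(fit_pred, y_pred),
    rmse_pred = rmse(fit_pred, y_pred),
    predictions = list(
      calibration = data.frame(sample_id = peaks_cal$sample_ids,
                               actual = y_cal, predicted = fit_cal),
      prediction = data.frame(sample_id = peaks_pred$sample_ids,
                              actual = y_pred, predicted = fit_pred))),
    class = "evaluation_report", model = model, kept = which(keep))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> %s / %s: %d LV, %d vars | ",
           "cal r=%.3f RMSE=%.1f%% | CV r=%.3f RMSE=%.1f%% | ",
           "pred r=%.3f RMSE=%.1f%%\n"),
    x$adulterant, x$method, x$n_LV, x$n_vars,
    x$r_cal, 100 * x$rmse_cal, x$r_cv, 100 * x$rmse_cv,
    x$r_pred, 100 * x$rmse_pred))
  invisible(x)
}

#' Refit a PLSR model on the selected variable subset
#'
#' Restricts the peak tables to the variables of a selection mask, then
#' reruns the full autoscale + SIMPLS + 10-fold cross-validation workflow
#' (the reduced model's latent-variable count is re-chosen by CV, so it may
#' differ from the full model's).
#'
#' @param peaks_cal,peaks_pred Calibration and prediction `peak_table`s.
#' @param selection A `selection_result` whose mask has at least one
#'   selected variable.
#' @param cv_seed Seed for the cross-validation fold assignment.
#' @param adulterant Label recorded in the report.
#' @param A_max,cv_folds Cross-validation settings.
#' @return An `evaluation_report` labelled `"<method>-PLSR"`.
#' @export
refit_selected <- function(peaks_cal, peaks_pred, selection, cv_seed = 1L,
                           adulterant = "adulterant", A_max = 10L,
                           cv_folds = 10L) {
  stopifnot(inherits(selection, "selection_result"))
  if (selection$n_selected < 1L) stop_("selection mask is empty")
  evaluate_pls(peaks_cal, peaks_pred, mask = selection$mask,
               method = paste0(selection$method, "-PLSR"),
               adulterant = adulterant, A_max = A_max,
               cv_folds = cv_folds, seed = cv_seed)
}
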