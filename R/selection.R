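#' Selection-result container
#'
#' @param method One of `"GA"`, `"VIP"`, `"SR"`.
#' @param scores Per-variable importance values (named).
#' @param threshold Scalar decision threshold (VIP: 1; SR: the F critical
#'   value; GA: the inclusion-frequency cutoff).
#' @param mask Logical per-variable selection mask.
#' @return Object of class `selection_result` with the above fields plus
#'   `n_selected`.
#' @export
selection_result <- function(method, scores, threshold, mask) {
  method <- match.arg(method, c("GA", "VIP", "SR"))
  stopifnot(length(scores) == length(mask))
  structure(list(method = method, scores = scores, threshold = threshold,
                 mask = as.logical(mask),
                 n_selected = sum(mask, na.rm = TRUE)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d/%d variables (threshold %.4g)\n",
              x$method, x$n_selected, length(x$mask), x$threshold))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Accumulates the squared, normalized PLS weights over the model's factors,
#' each weighted by the share of response variance that factor explains:
#' `VIP_j = sqrt(p * sum_a SS_a * (w_aj / ||w_a||)^2 / sum_a SS_a)` with
#' `SS_a = q_a^2 * t_a't_a`.  The scores satisfy the exact identity
#' `sum_j VIP_j^2 = p`, which motivates the classical greater-than-one
#' selection rule.
#'
#' @param model A fitted `pls_model`.
#' @return Named numeric vector of VIP scores (one per predictor).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  ss <- model$q^2 * colSums(model$T^2)     # y-variance explained per factor
  if (sum(ss) <= 0) stop_("model explains zero response variance")
  W2 <- model$W^2                          # columns already unit-norm
  scores <- sqrt(p * as.numeric(W2 %*% ss) / sum(ss))
  names(scores) <- rownames(model$W) %||% names(model$b)
  scores
}

#' @rdname vip_scores
#' @param threshold Selection threshold (default 1, the classical rule).
#' @export
vip_select <- function(model, threshold = 1) {
  scores <- vip_scores(model)
  selection_result("VIP", scores, threshold, scores > threshold)
}

#' Selectivity ratio via target projection
#'
#' Projects the autoscaled predictor matrix onto the normalized regression
#' vector (`t_TP = Xs b / ||b||`, `p_TP = Xs' t_TP / t_TP't_TP`); the
#' explained part of each variable is the corresponding column of
#' `t_TP p_TP'`, and the selectivity ratio is the per-variable ratio of
#' explained to residual squared norm.  A variable with zero residual is
#' reported as `Inf` with a warning — it sorts above any threshold.
#'
#' @param model A fitted `pls_model`.
#' @param X Calibration predictor matrix in raw units (the matrix the model
#'   was fitted on).
#' @return Named non-negative numeric vector of SR scores.
#' @export
selectivity_ratio_scores <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  Xs <- autoscale_apply(model$scaler_X, as.matrix(X))
  b <- model$b
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop_("regression vector is zero; SR undefined")
  t_tp <- Xs %*% (b / nb)
  p_tp <- crossprod(Xs, t_tp) / sum(t_tp^2)
  Xhat <- t_tp %*% t(p_tp)
  expl <- colSums(Xhat^2)
  resid <- colSums((Xs - Xhat)^2)
  zero <- resid <= .Machine$double.eps * pmax(expl, 1)
  if (any(zero))
    warn_("%d variable(s) have zero residual variance; SR set to Inf",
          sum(zero))
  scores <- ifelse(zero, Inf, expl / resid)
  names(scores) <- names(model$b) %||% colnames(X)
  scores
}

#' F-test critical value for the selectivity ratio
#'
#' Upper-`alpha` quantile of the F distribution with `(n_cal - 2,
#' n_cal - 3)` degrees of freedom — the 95\% criterion used to threshold SR
#' scores.  At the 63-sample calibration design this evaluates to 1.532
#' (3 d.p.).
#'
#' @param n_cal Number of calibration samples (>= 5).
#' @param alpha Significance level (default 0.05).
#' @return Scalar critical value.
#' @examples
#' round(sr_critical_value(63), 3)   # 1.532
#' @export
sr_critical_value <- function(n_cal, alpha = 0.05) {
  if (!is_count(n_cal) || n_cal < 5L)
    stop_("n_cal must be an integer >= 5")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_("alpha must lie in (0, 1)")
  qf(1 - alpha, df1 = n_cal - 2L, df2 = n_cal - 3L)
}

#' @rdname selectivity_ratio_scores
#' @param n_cal Calibration size used for the F-test threshold (defaults to
#'   the model's calibration size).
#' @param alpha Significance level of the F criterion.
#' @export
sr_select <- function(model, X, n_cal = nrow(model$T), alpha = 0.05) {
  scores <- selectivity_ratio_scores(model, X)
  thr <- sr_critical_value(n_cal, alpha)
  selection_result("SR", scores, thr, scores > thr)
}
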