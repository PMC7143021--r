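#' Model performance metrics
#'
#' `pearson_r()` is the Pearson correlation between predicted and actual
#' values; `rmse()` is the root-mean-square error
#' `sqrt(mean((pred - actual)^2))`, reported in fraction units (rendered as
#' percent in formatted reports).
#'
#' @param y_pred,y_true Equal-length numeric vectors (length >= 2).
#' @return A scalar.
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6))    # 1
#' rmse(c(0.1, 0.2), c(0.2, 0.3))       # 0.1
#' @export
pearson_r <- function(y_pred, y_true) {
  check_pair(y_pred, y_true)
  if (sd(y_pred) == 0 || sd(y_true) == 0)
    stop_("correlation undefined for constant input")
  cor(y_pred, y_true)
}

#' @rdname pearson_r
#' @export
rmse <- function(y_pred, y_true) {
  check_pair(y_pred, y_true)
  sqrt(mean((y_pred - y_true)^2))
}

check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop_("vectors have different lengths (%d vs %d)", length(a), length(b))
  if (length(a) < 2L) stop_("need at least 2 values")
  if (anyNA(a) || anyNA(b)) stop_("missing values not allowed")
  invisible(NULL)
}

#' Univariate regression of adulterant content on one peak intensity
#'
#' Ordinary least squares of the fraction on a single line's intensity,
#' evaluated with the Pearson correlation and the RMSE of the fit on the
#' same samples.  The correlation is kept signed here; tabular reports
#' render its magnitude (the conventional unsigned presentation).
#'
#' @param x Peak intensities (length >= 3, non-constant).
#' @param y Adulterant fractions, same length.
#' @return Object of class `univariate_result`: `slope`, `intercept`, `r`
#'   (signed), `rmse`.
#' @export
ols_univariate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_("x and y have different lengths (%d vs %d)", length(x), length(y))
  if (length(x) < 3L) stop_("need at least 3 samples")
  if (sd(x) == 0) stop_("predictor is constant; univariate fit undefined")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  pred <- slope * x + intercept
  structure(list(slope = slope, intercept = intercept,
                 r = cor(x, y), rmse = sqrt(mean((pred - y)^2))),
            class = "univariate_result")
}
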