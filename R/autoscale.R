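#' Autoscaling (mean-centre, unit variance)
#'
#' Standard chemometric preprocessing: each variable is mean-centred and
#' divided by its standard deviation (n-1 denominator).  `autoscale_fit()`
#' learns the column means/SDs, `autoscale_apply()` applies them (also to
#' new data), and `autoscale_invert()` undoes the transformation exactly.
#'
#' @param X Numeric matrix (samples x variables).
#' @return `autoscale_fit()` returns an object of class `scaler` with
#'   fields `means` and `sds`.
#' @examples
#' sc <- autoscale_fit(matrix(c(1, 3), ncol = 1))
#' autoscale_apply(sc, matrix(c(1, 3), ncol = 1))  # -0.7071, +0.7071
#' @export
autoscale_fit <- function(X) {
  X <- as.matrix(X)
  means <- colMeans(X)
  sds <- apply(X, 2L, sd)
  zero <- which(!(sds > 0))
  if (length(zero) > 0L) {
    nm <- colnames(X)[zero[1L]] %||% as.character(zero[1L])
    stop_("variable '%s' has zero variance and cannot be autoscaled",
          if (is.null(colnames(X))) as.character(zero[1L]) else nm)
  }
  structure(list(means = means, sds = sds), class = "scaler")
}

#' @rdname autoscale_fit
#' @param scaler A fitted `scaler`.
#' @export
autoscale_apply <- function(scaler, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$means))
    stop_("X has %d columns but scaler was fitted on %d variables",
          ncol(X), length(scaler$means))
  sweep(sweep(X, 2L, scaler$means, "-"), 2L, scaler$sds, "/")
}

#' @rdname autoscale_fit
#' @param Xs A matrix in scaled units.
#' @export
autoscale_invert <- function(scaler, Xs) {
  Xs <- as.matrix(Xs)
  if (ncol(Xs) != length(scaler$means))
    stop_("Xs has %d columns but scaler was fitted on %d variables",
          ncol(Xs), length(scaler$means))
  sweep(sweep(Xs, 2L, scaler$sds, "*"), 2L, scaler$means, "+")
}
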