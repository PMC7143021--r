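## SIMPLS core on an already autoscaled X and centred y.
## de Jong's algorithm for a single response: the cross-product s = X'y is
## deflated against an orthonormal basis V of the X-loadings; each weight
## r_a is the deflated s, scores are normalized to unit length.
## Returns components up to min(A, achievable rank) with achieved count.
simpls_core <- function(Xs, yc, A, tol = 1e-10) {
  n <- nrow(Xs); p <- ncol(Xs)
  R <- P <- V <- matrix(0, p, A)
  W <- matrix(0, p, A)          # normalized weight directions (for VIP)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  s <- crossprod(Xs, yc)
  s_ref <- sqrt(sum(s^2))       # initial cross-product magnitude
  x_ref <- sqrt(sum(Xs^2))      # Frobenius norm of the predictors
  achieved <- 0L
  for (a in seq_len(A)) {
    r <- s
    nr <- sqrt(sum(r^2))
    if (nr <= tol * max(s_ref, .Machine$double.eps)) break  # s exhausted
    t <- Xs %*% r
    normt <- sqrt(sum(t^2))
    if (normt <= tol * nr * max(x_ref, .Machine$double.eps)) break
    t <- t / normt
    r <- r / normt
    pl <- crossprod(Xs, t)
    qa <- sum(yc * t)
    v <- pl
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps^0.5) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; P[, a] <- pl; V[, a] <- v; Tm[, a] <- t; q[a] <- qa
    W[, a] <- r / sqrt(sum(r^2))
    achieved <- a
  }
  if (achieved == 0L) stop_("X has no usable variance (rank 0)")
  idx <- seq_len(achieved)
  list(A = achieved,
       R = R[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       W = W[, idx, drop = FALSE], T = Tm[, idx, drop = FALSE],
       q = q[idx])
}

#' Fit a SIMPLS partial least squares regression model
#'
#' Fits a single-response PLS1 model with de Jong's SIMPLS algorithm.  The
#' predictors are autoscaled (mean-centred, unit variance, n-1 denominator)
#' and the response is mean-centred but not variance-scaled; both scalings
#' are stored in the model so that [pls_predict()] accepts raw-unit data.
#'
#' @param X Numeric matrix n x p of raw peak intensities.
#' @param y Numeric response vector (adulterant fraction), length n.
#' @param A Number of latent variables, `1 <= A <= min(n-1, p)`.
#' @return Object of class `pls_model` with fields `A`, `R` (weight matrix,
#'   p x A, scores are `Xs %*% R`), `P` (X-loadings), `q` (y-loadings),
#'   `W` (unit-norm weight directions), `T` (calibration scores, unit
#'   length, mutually orthogonal), `b` (regression vector in scaled space,
#'   `b = R %*% q`), `scaler_X`, `y_center` and `fitted` (raw y units).
#' @seealso [pls_predict()], [kfold_cv()]
#' @export
simpls_fit <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_("X has %d rows but y has %d values", n, length(y))
  if (!is_count(A) || A > min(n - 1L, p))
    stop_("A must be an integer in [1, min(n-1, p)] = [1, %d]", min(n - 1L, p))
  scaler <- autoscale_fit(X)
  Xs <- autoscale_apply(scaler, X)
  y_center <- mean(y)
  yc <- y - y_center
  core <- simpls_core(Xs, yc, A)
  if (core$A < A)
    stop_("rank deficiency: only %d factor(s) achievable, %d requested",
          core$A, A)
  b <- core$R %*% core$q
  fitted <- as.numeric(Xs %*% b) + y_center
  structure(list(A = core$A, R = core$R, P = core$P, W = core$W,
                 T = core$T, q = core$q, b = as.numeric(b),
                 scaler_X = scaler, y_center = y_center, fitted = fitted),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors\n",
              x$A, length(x$b)))
  invisible(x)
}

#' Predict adulterant fractions from a fitted PLS model
#'
#' Applies the stored autoscaling to the new predictor matrix, multiplies by
#' the regression vector and adds back the response centre.  Prediction on
#' the calibration matrix reproduces the stored fitted values.
#'
#' @param model A `pls_model`.
#' @param X_new Matrix in raw intensity units with the model's p columns.
#' @param A Optional number of latent variables to use (`<= model$A`);
#'   defaults to all fitted factors.
#' @return Numeric vector of predictions.
#' @export
pls_predict <- function(model, X_new, A = model$A) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$b))
    stop_("X_new has %d columns but the model expects %d",
          ncol(X_new), length(model$b))
  if (!is_count(A) || A > model$A)
    stop_("A must be an integer in [1, %d]", model$A)
  Xs <- autoscale_apply(model$scaler_X, X_new)
  idx <- seq_len(A)
  b <- model$R[, idx, drop = FALSE] %*% model$q[idx]
  as.numeric(Xs %*% b) + model$y_center
}

## predictions for every factor count 1..model$A at once (n_new x A matrix);
## cheap because the per-factor contributions are cumulative
pls_predict_all <- function(model, X_new) {
  Xs <- autoscale_apply(model$scaler_X, as.matrix(X_new))
  Tn <- Xs %*% model$R                       # n x A new scores
  contrib <- sweep(Tn, 2L, model$q, "*")
  preds <- t(apply(contrib, 1L, cumsum))
  if (model$A == 1L) preds <- matrix(contrib, ncol = 1L)
  preds + model$y_center
}

#' K-fold cross-validation for the number of latent variables
#'
#' Random 10-fold cross-validation (seeded) of the SIMPLS model: for each
#' candidate factor count `A` in `1..A_max`, RMSECV is the root mean squared
#' error over all held-out samples, where each fold's model — including its
#' autoscaling — is refitted on the remaining folds only (no leakage).  The
#' chosen `A` is the smallest factor count attaining the minimum RMSECV
#' (within a tiny relative tie tolerance), which guards against overfitting
#' when several counts are statistically equivalent.
#'
#' @param X,y Calibration predictors (raw units) and response.
#' @param A_max Largest factor count to consider; silently capped (with a
#'   warning) at the rank achievable in every training fold.
#' @param k Number of folds (default 10); `k = n` gives leave-one-out.
#' @param seed Integer seed for the random fold assignment, or `NULL`.
#' @param folds Optional explicit per-sample fold assignment (overrides
#'   `k`/`seed`).
#' @return Object of class `cv_result`: `rmsecv_by_A`, `chosen_A`,
#'   `fold_assignments`, `A_max` (possibly capped), `seed`.
#' @export
kfold_cv <- function(X, y, A_max = 10L, k = 10L, seed = NULL, folds = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(folds)) {
    if (!is_count(k) || k < 2L || k > n)
      stop_("k must be an integer in [2, n]")
    assign_folds <- function() sample(rep(seq_len(k), length.out = n))
    folds <- if (is.null(seed)) assign_folds() else
      withr::with_seed(fold_seed(seed), assign_folds())
  } else {
    folds <- as.integer(folds)
    stopifnot(length(folds) == n)
    k <- max(folds)
  }
  min_train <- n - max(tabulate(folds, nbins = k))
  A_cap <- min(A_max, p, min_train - 1L)
  if (A_cap < 1L) stop_("folds leave too few training samples")

  preds <- matrix(NA_real_, n, A_cap)
  achieved <- A_cap
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(!tr)) next
    scaler <- autoscale_fit(X[tr, , drop = FALSE])
    Xs <- autoscale_apply(scaler, X[tr, , drop = FALSE])
    yc_mean <- mean(y[tr])
    core <- simpls_core(Xs, y[tr] - yc_mean, A_cap)
    achieved <- min(achieved, core$A)
    Xts <- autoscale_apply(scaler, X[!tr, , drop = FALSE])
    Tn <- Xts %*% core$R
    contrib <- sweep(Tn, 2L, core$q, "*")
    cum <- if (core$A == 1L) matrix(contrib, ncol = 1L) else
      t(apply(contrib, 1L, cumsum))
    preds[!tr, seq_len(core$A)] <- cum + yc_mean
  }
  if (achieved < A_cap) {
    warn_("A_max capped at %d (rank achievable in every training fold)",
          achieved)
    A_cap <- achieved
    preds <- preds[, seq_len(A_cap), drop = FALSE]
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  ## smallest A within a hair of the global minimum: on exactly low-rank
  ## data all counts tie to rounding error and the smallest must win
  m <- min(rmsecv)
  chosen <- which(rmsecv <= m * (1 + 1e-8) + 1e-12)[1L]
  structure(list(rmsecv_by_A = rmsecv, chosen_A = as.integer(chosen),
                 fold_assignments = folds, A_max = A_cap, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> chosen A = %d; RMSECV = %s\n", x$chosen_A,
              paste(signif(x$rmsecv_by_A, 4), collapse = ", ")))
  invisible(x)
}
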