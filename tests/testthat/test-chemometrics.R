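test_that("autoscaling centres, scales and inverts exactly", {
  sc <- autoscale_fit(matrix(c(1, 3), ncol = 1))
  expect_equal(as.numeric(autoscale_apply(sc, matrix(c(1, 3), ncol = 1))),
               c(-1, 1) / sqrt(2))
  X <- withr::with_seed(21L, matrix(rnorm(63 * 43, 5, 2), 63, 43))
  sc <- autoscale_fit(X)
  Xs <- autoscale_apply(sc, X)
  expect_lt(max(abs(colMeans(Xs))), 1e-10)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-10)
  expect_equal(autoscale_invert(sc, Xs), X, tolerance = 1e-12)
  bad <- X
  bad[, 7L] <- 2
  colnames(bad) <- paste0("v", 1:43)
  expect_error(autoscale_fit(bad), "v7")
})

test_that("univariate OLS matches closed forms and an lm oracle", {
  fit <- ols_univariate(c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$intercept, 0, tolerance = 1e-14)
  expect_equal(fit$r, 1)
  x <- c(0.2, 1.4, 2.2, 3.9)
  fit <- ols_univariate(x, 0.5 * x)
  expect_equal(fit$r, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-14)
  ## seeded random instance against lm()
  withr::with_seed(31L, {
    x <- rnorm(40); y <- rnorm(40)
  })
  fit <- ols_univariate(x, y)
  lmfit <- lm(y ~ x)
  expect_equal(fit$slope, unname(coef(lmfit)[2L]))
  expect_equal(fit$intercept, unname(coef(lmfit)[1L]))
  expect_equal(fit$r, cor(x, y))
  expect_equal(fit$rmse, sqrt(mean(residuals(lmfit)^2)))
  expect_error(ols_univariate(rep(2, 10), rnorm(10)), "constant")
})

test_that("SIMPLS agrees with an independent NIPALS PLS1 oracle", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    si <- scale_instance(inst)
    for (A in c(1L, 3L, 5L)) {
      model <- simpls_fit(inst$X, inst$y, A)
      oracle <- nipals_pls1(si$Xs, si$yc, A)
      expect_equal(model$fitted,
                   oracle$predict(si$Xs) + mean(inst$y),
                   tolerance = 1e-8)
    }
  }
})

test_that("full-factor SIMPLS reproduces the OLS fit", {
  inst <- random_instance(77L, n = 25L, p = 6L, rank = 6L, noise = 1)
  model <- simpls_fit(inst$X, inst$y, 6L)
  ols <- lm(inst$y ~ inst$X)
  expect_equal(model$fitted, unname(fitted(ols)), tolerance = 1e-8)
})

test_that("PLS scores are orthogonal and b = R q", {
  for (seed in c(2L, 9L)) {
    inst <- random_instance(seed, n = 40L, p = 12L, rank = 4L)
    model <- simpls_fit(inst$X, inst$y, 4L)
    G <- crossprod(model$T)
    off <- abs(G[upper.tri(G)]) / max(diag(G))
    expect_lt(max(off), 1e-8)
    expect_equal(model$b, as.numeric(model$R %*% model$q))
    expect_lte(model$A, min(nrow(inst$X) - 1L, ncol(inst$X)))
  }
})

test_that("rank deficiency and bad factor counts are rejected", {
  f <- seq(0, 1, by = 0.25)
  X <- cbind(a = 1 + 2 * f, b = 3 - f, c = 0.5 + f)  # rank 1 centred
  expect_error(simpls_fit(X, f, 3L), "rank deficiency")
  inst <- random_instance(1L)
  expect_error(simpls_fit(inst$X, inst$y, 0), "A must be")
  expect_error(simpls_fit(inst$X, inst$y, 100L), "A must be")
})

test_that("prediction is consistent, duplicable and interpolates exactly", {
  inst <- random_instance(4L)
  model <- simpls_fit(inst$X, inst$y, 3L)
  expect_equal(pls_predict(model, inst$X), model$fitted)
  dup <- inst$X[c(1L, 1L), , drop = FALSE]
  pr <- pls_predict(model, dup)
  expect_identical(pr[1L], pr[2L])
  expect_error(pls_predict(model, inst$X[, 1:3]), "columns")

  ## noiseless mixtures: a fraction off the design grid is recovered
  ds <- noiseless_dataset(seed = 10L)
  peaks <- build_peak_table(ds$calibration, ds$lines)
  keep <- apply(peaks$intensities, 2L, sd) >
    1e-10 * pmax(apply(abs(peaks$intensities), 2L, max), 1)
  model <- simpls_fit(peaks$intensities[, keep], peaks$fractions, 1L)
  expect_lt(max(abs(model$fitted - peaks$fractions)), 1e-8)
  pure <- make_endmember_profile("acacia", 10L)
  adu <- make_endmember_profile("hfcs55", 10L)
  off_design <- render_spectrum(mix_profiles(pure, adu, 0.37),
                                grid_step_nm = 0.1, baseline = 1,
                                fraction = 0.37)
  x_new <- build_peak_table(list(off_design), ds$lines)$intensities[, keep,
                                                                    drop = FALSE]
  expect_equal(pls_predict(model, x_new), 0.37, tolerance = 1e-6)
})

test_that("cross-validation picks one factor on exact one-factor data", {
  ds <- noiseless_dataset(seed = 13L)
  peaks <- build_peak_table(ds$calibration, ds$lines)
  keep <- apply(peaks$intensities, 2L, sd) >
    1e-10 * pmax(apply(abs(peaks$intensities), 2L, max), 1)
  cv <- suppressWarnings(kfold_cv(peaks$intensities[, keep],
                                  peaks$fractions, A_max = 5L, seed = 2L))
  expect_lt(cv$rmsecv_by_A[1L], 1e-6)
  expect_equal(cv$chosen_A, 1L)
})

test_that("leave-one-out CV equals a brute-force refit oracle", {
  inst <- random_instance(15L, n = 6L, p = 3L, rank = 2L, noise = 0.5)
  cv <- kfold_cv(inst$X, inst$y, A_max = 2L, k = 6L, seed = 5L)
  for (A in 1:2) {
    errs <- vapply(seq_len(6L), function(i) {
      m <- simpls_fit(inst$X[-i, ], inst$y[-i], A)
      pls_predict(m, inst$X[i, , drop = FALSE]) - inst$y[i]
    }, 0.0)
    expect_equal(cv$rmsecv_by_A[A], sqrt(mean(errs^2)), tolerance = 1e-10)
  }
  ## seeded fold assignment is reproducible
  cv2 <- kfold_cv(inst$X, inst$y, A_max = 2L, k = 6L, seed = 5L)
  expect_identical(cv$fold_assignments, cv2$fold_assignments)
  expect_identical(cv$rmsecv_by_A, cv2$rmsecv_by_A)
})

test_that("cross-validation is pessimistic relative to the training fit", {
  ## on noisy data, held-out error should exceed calibration error on
  ## average over seeds
  diffs <- vapply(1:5, function(seed) {
    inst <- random_instance(seed, n = 40L, p = 15L, rank = 3L, noise = 1)
    cv <- kfold_cv(inst$X, inst$y, A_max = 5L, seed = seed)
    model <- simpls_fit(inst$X, inst$y, cv$chosen_A)
    cv$rmsecv_by_A[cv$chosen_A] - rmse(model$fitted, inst$y)
  }, 0.0)
  expect_gt(mean(diffs), 0)
})

test_that("performance metrics match their definitions", {
  y <- c(0.1, 0.4, 0.9)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(pearson_r(y + 0.1, y), 1)
  expect_equal(rmse(y + 0.1, y), 0.1)
  withr::with_seed(61L, {
    a <- rnorm(50); b <- rnorm(50)
  })
  expect_equal(pearson_r(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 50))
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(rmse(1:3, 1:4), "lengths")
})
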