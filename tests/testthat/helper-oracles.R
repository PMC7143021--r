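## Independent reference implementations and shared fixtures.
## These oracles deliberately avoid the package's SIMPLS code path.

## NIPALS PLS1 on an autoscaled X and centred y; returns fitted values and
## a prediction function for new (already scaled/centred) data.
nipals_pls1 <- function(Xs, yc, A) {
  E <- Xs; f <- yc
  p <- ncol(Xs)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    tt <- sum(t^2)
    pa <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pa)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(b = as.numeric(b),
       predict = function(Xnew_s) as.numeric(Xnew_s %*% b))
}

## random regression instance: low-rank signal plus noise, no constant cols
random_instance <- function(seed, n = 30L, p = 8L, rank = 3L,
                            noise = 0.3) {
  withr::with_seed(seed, {
    S <- matrix(rnorm(n * rank), n, rank)
    L <- matrix(rnorm(rank * p), rank, p)
    X <- S %*% L + noise * matrix(rnorm(n * p), n, p)
    y <- as.numeric(S %*% rnorm(rank)) + noise * rnorm(n)
    list(X = X, y = y)
  })
}

## scaled/centred view of an instance (the problem both PLS variants see)
scale_instance <- function(inst) {
  sc <- autoscale_fit(inst$X)
  list(Xs = autoscale_apply(sc, inst$X), yc = inst$y - mean(inst$y))
}

## small noiseless dataset on a coarse grid (fast; linear mixing intact)
noiseless_dataset <- function(seed = 1L, pure = "acacia",
                              adulterant = "hfcs55",
                              design = mixture_design()) {
  generate_dataset(pure, adulterant, design = design,
                   noise = noise_config(sigma_shot = 0), seed = seed,
                   grid_step_nm = 0.1)
}

## dataset with designated informative lines: the adulterant differs from
## pure acacia honey ONLY at the mineral lines (Mg/Ca/Na/K); every other
## line is identical between endmembers, hence pure measurement noise
designated_dataset <- function(seed, noise = noise_config()) {
  pure <- make_endmember_profile("acacia", seed = seed)
  adu <- make_endmember_profile("hfcs55", seed = seed)
  mineral <- line_element() %in% c("Mg", "Ca", "Na", "K")
  adu$amplitudes[!mineral] <- pure$amplitudes[!mineral]
  ds <- generate_from_profiles(pure, adu, noise = noise, seed = seed)
  list(ds = ds, informative = which(mineral))
}

mineral_lines <- function() which(line_element() %in%
                                    c("Mg", "Ca", "Na", "K"))

peaks_of <- function(ds) list(
  cal = build_peak_table(ds$calibration, ds$lines),
  pred = build_peak_table(ds$prediction, ds$lines))
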