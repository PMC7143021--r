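test_that("line library holds the 43 ascending emission lines", {
  lib <- libs_line_library()
  expect_equal(nrow(lib), 43L)
  expect_true(all(diff(lib$wavelength_nm) > 0))
  expect_equal(lib$wavelength_nm[1L], 247.88)
  expect_equal(lib$wavelength_nm[43L], 859.49)
  expect_true(all(lib$wavelength_nm >= 240 & lib$wavelength_nm <= 860))
  expect_equal(lib$species[lib$wavelength_nm == 279.58], "Mg II")
  expect_equal(sum(lib$species == "Unknown"), 4L)
  expect_equal(lib$index, 1:43)
})

test_that("endmember profiles respect the honey/HFCS spectral contrasts", {
  grp <- line_element()
  for (seed in c(1L, 7L, 123L)) {
    profs <- lapply(c("acacia", "rape", "hfcs55", "hfcs90"),
                    make_endmember_profile, seed = seed)
    names(profs) <- c("acacia", "rape", "hfcs55", "hfcs90")
    for (pf in profs) expect_true(all(pf$amplitudes >= 0))
    ## minerals present only in honeys
    for (k in c("hfcs55", "hfcs90"))
      expect_true(all(profs[[k]]$amplitudes[grp %in% c("Mg", "Ca", "K")]
                      == 0))
    ## Na strictly stronger in acacia than rape
    expect_true(all(profs$acacia$amplitudes[grp == "Na"] >
                      profs$rape$amplitudes[grp == "Na"]))
    ## organic emissions present everywhere
    for (pf in profs)
      expect_true(all(pf$amplitudes[grp %in% c("C", "H", "O", "N", "CN")]
                      > 0))
    ## shared background lines identical across endmembers at one seed
    expect_identical(profs$acacia$amplitudes[grp %in% c("Si", "Unknown")],
                     profs$hfcs90$amplitudes[grp %in% c("Si", "Unknown")])
  }
  expect_identical(make_endmember_profile("acacia", 5L),
                   make_endmember_profile("acacia", 5L))
  expect_error(make_endmember_profile("clover", 1L), "unknown endmember")
})

test_that("linear mixing is exact at the endpoints and midpoint", {
  a <- make_endmember_profile("acacia", 3L)
  h <- make_endmember_profile("hfcs90", 3L)
  expect_equal(mix_profiles(a, h, 0)$amplitudes, a$amplitudes)
  expect_equal(mix_profiles(a, h, 1)$amplitudes, h$amplitudes)
  mid <- mix_profiles(a, h, 0.5)
  expect_equal(mid$amplitudes, (a$amplitudes + h$amplitudes) / 2)
  ## a zeroed adulterant line halves under 50/50 mixing
  k_line <- which(line_element() == "K")[1L]
  expect_equal(unname(mid$amplitudes[k_line]),
               unname(a$amplitudes[k_line]) / 2)
  expect_error(mix_profiles(a, h, 1.2), "fraction")
  expect_error(mix_profiles(a, h, -0.1), "fraction")
})

test_that("rendering realizes Gaussian peaks on a baseline", {
  a <- make_endmember_profile("acacia", 1L)
  ## single isolated peak: amplitude 10 at the Na 589.03 line
  single <- a
  single$amplitudes[] <- 0
  na1 <- which(abs(a$lines$wavelength_nm - 589.03) < 0.01)
  single$amplitudes[na1] <- 10
  sp <- render_spectrum(single, baseline = 1)
  imax <- which.max(sp$intensity)
  expect_lt(abs(sp$grid_nm[imax] - 589.03), 0.051)
  ## the line centre sits up to half a grid step off-grid, so the sampled
  ## maximum is attenuated by at most exp(-(step/2)^2 / (2 sigma^2)) ~ 2%
  expect_equal(max(sp$intensity), 11, tolerance = 0.02)
  ## on-grid line: sampled maximum hits baseline + amplitude exactly
  on_grid <- a
  on_grid$amplitudes[] <- 0
  mg <- which(a$lines$wavelength_nm == 285.25)
  on_grid$amplitudes[mg] <- 10
  expect_equal(max(render_spectrum(on_grid, baseline = 1)$intensity), 11,
               tolerance = 1e-6)
  ## far from any line the spectrum sits on the baseline
  expect_equal(sp$intensity[sp$grid_nm < 500], rep(1, sum(sp$grid_nm < 500)))
  ## all-zero profile renders flat
  single$amplitudes[na1] <- 0
  flat <- render_spectrum(single, baseline = 2.5)
  expect_true(all(flat$intensity == 2.5))
  ## the Na doublet resolves into two local maxima at FWHM 0.3
  doublet <- a
  doublet$amplitudes[] <- 0
  doublet$amplitudes[line_element() == "Na"] <- c(10, 8)
  spd <- render_spectrum(doublet, peak_fwhm_nm = 0.3)
  win <- which(spd$grid_nm > 588.5 & spd$grid_nm < 590.2)
  y <- spd$intensity[win]
  n_max <- sum(diff(sign(diff(y))) == -2)
  expect_equal(n_max, 2L)
  expect_error(render_spectrum(a, grid_step_nm = -1), "positive")
  expect_error(render_spectrum(a, peak_fwhm_nm = 0), "positive")
  expect_error(render_spectrum(a, grid_step_nm = 0.2, peak_fwhm_nm = 0.3),
               "too coarse")
})

test_that("shot averaging shrinks noise by sqrt(n) and is seeded", {
  sp <- libs_spectrum(seq_len(10000), rep(100, 10000), "flat")
  ## sigma 0 leaves the spectrum untouched
  expect_identical(simulate_measurement(sp, noise_config(sigma_shot = 0)),
                   sp)
  ## sigma 1 over 100 shots: empirical pixel SD close to 0.1
  out <- simulate_measurement(sp, noise_config(sigma_shot = 1,
                                               n_shots = 100L, seed = 42L))
  emp_sd <- sd(out$intensity - sp$intensity)
  expect_gt(emp_sd, 0.085)
  expect_lt(emp_sd, 0.115)
  ## same seed reproduces bit-identically; clipping keeps intensities >= 0
  out2 <- simulate_measurement(sp, noise_config(sigma_shot = 1,
                                                n_shots = 100L, seed = 42L))
  expect_identical(out, out2)
  low <- libs_spectrum(1:2000, rep(0, 2000), "zero")
  clipped <- simulate_measurement(low, noise_config(sigma_shot = 10,
                                                    n_shots = 4L,
                                                    seed = 1L))
  expect_true(all(clipped$intensity >= 0))
})

test_that("the default mixing design yields 63 + 39 samples", {
  ds <- noiseless_dataset(seed = 2L)
  expect_length(ds$calibration, 63L)
  expect_length(ds$prediction, 39L)
  expect_equal(sort(unique(vapply(ds$calibration, `[[`, 0.0, "fraction"))),
               seq(0, 1, by = 0.05))
  expect_equal(sort(unique(vapply(ds$prediction, `[[`, 0.0, "fraction"))),
               seq(0, 0.96, by = 0.08))
})

test_that("custom designs, degenerate inputs and determinism behave", {
  tiny <- mixture_design(calibration_levels = c(0, 1),
                         prediction_levels = 0.5, replicates = 1L)
  ds <- generate_dataset("acacia", "rape", design = tiny,
                         noise = noise_config(sigma_shot = 0.5,
                                              n_shots = 2L),
                         seed = 9L, grid_step_nm = 0.1)
  expect_length(ds$calibration, 2L)
  expect_equal(vapply(ds$calibration, `[[`, 0.0, "fraction"), c(0, 1))
  ## bit-identical regeneration under the same seed
  ds2 <- generate_dataset("acacia", "rape", design = tiny,
                          noise = noise_config(sigma_shot = 0.5,
                                               n_shots = 2L),
                          seed = 9L, grid_step_nm = 0.1)
  expect_identical(ds$calibration[[1L]]$intensity,
                   ds2$calibration[[1L]]$intensity)
  expect_error(generate_dataset("acacia", "acacia", design = tiny),
               "distinct")
  expect_error(
    generate_dataset("acacia", "rape",
                     design = mixture_design(calibration_levels = numeric(0))),
    "non-empty")
  expect_error(mixture_design(calibration_levels = c(-0.1, 0.5)), "0, 1")
})

test_that("noiseless mixture peak intensities are affine in the fraction", {
  ds <- noiseless_dataset(seed = 4L,
                          design = mixture_design(replicates = 1L))
  peaks <- build_peak_table(ds$calibration, ds$lines)
  f <- peaks$fractions
  for (j in seq_len(ncol(peaks$intensities))) {
    v <- peaks$intensities[, j]
    if (sd(v) <= 1e-10 * max(abs(v), 1)) next # shared background line
    fit <- ols_univariate(f, v)
    ss_res <- sum((fit$slope * f + fit$intercept - v)^2)
    ss_tot <- sum((v - mean(v))^2)
    expect_lt(ss_res / ss_tot, 1e-9)
  }
})
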