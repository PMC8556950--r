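test_that("resampling is the identity on the native axis and exact on linear ramps", {
  x <- seq(300, 1800, by = 1)
  set <- raman_spectra(x, 0.001 * x + 2)
  same <- resample(set, x)
  expect_equal(same$intensity, set$intensity, ignore_attr = TRUE)
  half <- resample(set, c(300, 1800, 0.5))
  expect_equal(half$intensity[1, ], 0.001 * seq(300, 1800, 0.5) + 2)
  expect_error(resample(set, c(300, 1900, 1)), "beyond")
})

test_that("despiking leaves smooth peaks alone and is idempotent", {
  x <- seq(300, 1800)
  y <- 5 * exp(-0.5 * ((x - 1000) / 6.37)^2) + 0.001 * x
  set <- raman_spectra(x, y)
  out <- despike(set)
  expect_equal(out$meta$n_spikes, 0L)
  expect_equal(out$intensity, set$intensity, ignore_attr = TRUE)
  again <- despike(out)
  expect_equal(again$intensity, out$intensity, ignore_attr = TRUE)
})

test_that("an injected cosmic spike is located exactly and repaired", {
  d <- small_dataset(n_per_class = 2, seed = 11, spike_rate = 0, noise_sd = 0.05)
  y <- d$spectra$intensity[1, ]
  truth <- d$truth$noise_free[1, ]
  hit <- 700L  # channel index
  y2 <- y
  y2[hit] <- y2[hit] + 50 * max(d$truth$amplitudes[1, ])
  set <- raman_spectra(d$spectra$wavenumber, y2)
  out <- despike(set)
  pos <- attr(out, "spike_positions")[[1]]
  expect_identical(pos, d$spectra$wavenumber[hit])
  noise_sd <- 0.05 * max(sapply(default_profiles(), function(p) max(p$amplitudes)))
  expect_lt(max(abs(out$intensity[1, ] - y)), 3 * noise_sd)
})

test_that("despike recovers >= 95% of generator-injected spikes", {
  d <- small_dataset(n_per_class = 25, seed = 13)
  out <- despike(d$spectra)
  injected <- d$truth$spike_positions
  detected <- attr(out, "spike_positions")
  n_inj <- sum(lengths(injected))
  n_hit <- sum(mapply(function(a, b) sum(a %in% b), injected, detected))
  expect_gt(n_inj, 10)
  expect_gte(n_hit / n_inj, 0.95)
})

test_that("baseline correction reconstructs the input and recovers known backgrounds", {
  x <- seq(300, 1800)
  # peakless first-degree polynomial: recovered to < 1% of its range
  lin <- raman_spectra(x, 2 + 0.001 * x)
  out <- baseline_correct(lin)
  expect_lt(max(abs(out$intensity)), 0.01 * diff(range(lin$intensity)))
  expect_equal(out$intensity + attr(out, "baseline"), lin$intensity,
               tolerance = 1e-9, ignore_attr = TRUE)
  # generator ground truth: RMSE < 5% of the mean true baseline
  d <- small_dataset(n_per_class = 8, seed = 21, spike_rate = 0)
  bc <- baseline_correct(d$spectra)
  est <- attr(bc, "baseline")
  rmse <- sqrt(mean((est - d$truth$baseline)^2))
  expect_lt(rmse, 0.05 * mean(d$truth$baseline))
  expect_equal(bc$intensity + est, d$spectra$intensity,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the raw asymmetric smoother stays a lower envelope on peak-dominated spectra", {
  d <- small_dataset(n_per_class = 4, seed = 31, spike_rate = 0)
  cfg <- preprocess_config(baseline_offset = FALSE)
  bc <- baseline_correct(d$spectra, cfg)
  est <- attr(bc, "baseline")
  frac_below <- mean(est <= d$spectra$intensity)
  expect_gte(frac_below, 0.90)
  # the default (offset-corrected) estimate sits above the raw envelope
  est2 <- attr(baseline_correct(d$spectra), "baseline")
  expect_gt(mean(est2 - est), 0)
})

test_that("area normalization hits the target integral, preserves shape and is idempotent", {
  x <- seq(300, 1800)
  const <- raman_spectra(x, rep(5, length(x)))
  out <- area_normalize(const)
  expect_equal(out$intensity[1, ], rep(1 / 1500, length(x)), tolerance = 1e-9)
  expect_equal(pracma::trapz(x, out$intensity[1, ]), 1, tolerance = 1e-9)
  # idempotence and scale invariance
  twice <- area_normalize(out)
  expect_equal(twice$intensity, out$intensity, tolerance = 1e-12, ignore_attr = TRUE)
  scaled <- const; scaled$intensity <- scaled$intensity * 7.3
  expect_equal(area_normalize(scaled)$intensity, out$intensity,
               tolerance = 1e-12, ignore_attr = TRUE)
  zero <- raman_spectra(x, rep(0, length(x)))
  expect_error(area_normalize(zero), "nonpositive")
})

test_that("the full chain normalizes every spectrum and is stable on its output", {
  d <- small_dataset(n_per_class = 5, seed = 17)
  clean <- preprocess(d$spectra)
  ints <- apply(clean$intensity, 1L, function(y) pracma::trapz(clean$wavenumber, y))
  expect_equal(ints, rep(1, n_spectra(clean)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true("n_spikes" %in% names(clean$meta))
  # rerunning the chain on its own output is stable: no spikes are found,
  # and intensities move only at the level of the baseline estimator's
  # residual response to noise, far below the peak scale
  again <- preprocess(clean)
  expect_equal(again$meta$n_spikes, rep(0L, n_spectra(clean)))
  expect_lt(mean(abs(again$intensity - clean$intensity)),
            0.01 * max(abs(clean$intensity)))
  # band areas move only at the few-percent level (the second baseline pass
  # digs slightly under the strongest peaks; preprocess raw spectra once)
  a1 <- integrate_band(clean, 993, 1013); a2 <- integrate_band(again, 993, 1013)
  expect_lt(max(abs(a2 - a1) / a1), 0.10)
  expect_error(preprocess(d$spectra[0]), "empty|rows")
})
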