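test_that("power spectra behave like a calibrated periodogram", {
  expect_equal(unname(compute_psd(rep(0, 500), 250)), rep(0, 35))
  expect_error(compute_psd(rnorm(50), 250), "64")
  # unit 10 Hz sinusoid: grid maximum at 10 Hz, sharp relative to 20 Hz
  x <- sin(2 * pi * 10 * (0:499) / 250)
  p <- compute_psd(x, 250)
  expect_equal(unname(which.max(p)), 10)
  expect_gt(p["10"] / p["20"], 100)
  # Parseval: integrated power over (0, Nyquist) recovers the variance
  set.seed(8)
  sigma <- 1.7
  tot <- replicate(50, {
    y <- rnorm(500, sd = sigma)
    sum(compute_psd(y, 250, freq_grid = 1:124))  # 1 Hz spacing -> sum = integral
  })
  expect_lt(abs(mean(tot) - sigma^2) / sigma^2, 0.15)
})

test_that("Fourier resampling is exact for band-limited periodic signals", {
  t0 <- (0:99) / 100
  x <- 2 * sin(2 * pi * 3 * t0 + 0.4) + cos(2 * pi * 7 * t0)
  for (m in c(100L, 150L, 237L, 73L)) {
    tm <- (0:(m - 1)) / m
    want <- 2 * sin(2 * pi * 3 * tm + 0.4) + cos(2 * pi * 7 * tm)
    expect_lt(max(abs(resample_fourier(x, m) - want)), 1e-10)
  }
  # matrix form resamples columns independently
  X <- cbind(x, 2 * x)
  Y <- resample_fourier(X, 150)
  expect_lt(max(abs(Y[, 2] - 2 * Y[, 1])), 1e-10)
})

test_that("IRASA contracts: default factors, errors, positivity", {
  h <- default_h_set()
  expect_length(h, 17)
  expect_equal(h[1], 1.10)
  expect_equal(h[17], 1.90)
  expect_equal(unique(round(diff(h), 10)), 0.05)
  expect_error(irasa_aperiodic(rnorm(500), 250, h_set = c(0.9, 1.1)),
               "exceed 1")
  expect_error(irasa_aperiodic(rnorm(80), 250), "too short|64 samples")
  ap <- irasa_aperiodic(rnorm(500), 250)
  expect_true(all(ap > 0))
})

test_that("log-log least squares recovers exact and noisy power laws", {
  f <- as.numeric(1:35)
  ones <- setNames(rep(1, 35), f)
  expect_equal(unname(fit_aperiodic(ones)), c(0, 0))
  law <- setNames(10 * f^(-2), f)
  expect_equal(unname(fit_aperiodic(law)), c(-2, 1), tolerance = 1e-12)
  set.seed(12)
  sl <- replicate(20, {
    noisy <- setNames(10^(1 - 1.7 * log10(f) + rnorm(35, sd = 0.25)), f)
    fit_aperiodic(noisy)["slope"]
  })
  expect_lt(abs(mean(sl) + 1.7), 0.15)
  neg <- setNames(c(rep(1, 34), -1), f)
  expect_error(fit_aperiodic(neg, 3, 35), "strictly positive")
})

test_that("band power is the inclusive grid mean", {
  f <- as.numeric(1:35)
  const <- setNames(rep(3.3, 35), f)
  expect_equal(band_power(const, 8, 13), 3.3)
  ramp <- setNames(f, f)
  expect_equal(band_power(ramp, 8, 13), 10.5)
  spike7 <- setNames(as.numeric(f == 7), f)
  expect_equal(band_power(spike7, 8, 13), 0)
  expect_error(band_power(const, 13, 8), "lo < hi")
  expect_error(band_power(const, 30, 40), "outside")
  expect_error(band_power(unname(const), 8, 13), "unnamed")
})

test_that("decomposition identity holds and oscillatory power can dip negative", {
  mont <- small_montage()
  ep <- generate_attention_epochs(small_config(seed = 21), mont)
  sp <- irasa_decompose(ep)
  expect_lt(max(abs(sp$mixed - sp$aperiodic - sp$oscillatory)) /
              max(sp$mixed), 1e-12)
  expect_true(all(sp$aperiodic > 0))
  expect_true(any(sp$oscillatory < 0))  # subtraction is not floored
})

test_that("feature extraction reproduces band definitions and identities", {
  mont <- small_montage()
  ep <- generate_attention_epochs(small_config(seed = 22), mont)
  sp <- irasa_decompose(ep)
  ft <- extract_features(sp)
  expect_lt(max(abs(ft$mix_alpha - ft$osc_alpha - ft$ap_alpha)) /
              max(abs(ft$mix_alpha)), 1e-12)
  # ap_broadband is the inclusive 3-30 Hz mean of the aperiodic spectrum
  i <- 5  # arbitrary trial
  ch <- match(ft$channel[i], sp$channels)
  expect_equal(ft$ap_broadband[i],
               mean(sp$aperiodic[ft$trial[i], ch, 3:30]))
  expect_equal(ft$osc_alpha[i],
               mean(sp$oscillatory[ft$trial[i], ch, 8:13]))
  # labels carried through in trial order
  expect_identical(feature_matrix(ft, "osc_alpha") |> attr("labels"),
                   ep$labels)
})

test_that("per-trial aperiodic slope tracks the generating exponent", {
  set.seed(31)
  srate <- 250; n <- 500
  x <- generate_aperiodic_background(2, 1, n, srate, n_series = 100)
  ep <- epoch_set(aperm(array(x, c(n, 100, 1)), c(2, 3, 1)), srate,
                  rep(1, 100), "ch1")
  ft <- extract_features(irasa_decompose(ep))
  expect_lt(abs(mean(ft$slope) + 2), 0.2)
})

test_that("power features are scale-equivariant", {
  set.seed(13)
  x <- generate_aperiodic_background(1.5, 0.5, 500, 250) +
    sin(2 * pi * 10 * (0:499) / 250)
  c0 <- 3.7
  p1 <- compute_psd(x, 250); p2 <- compute_psd(c0 * x, 250)
  expect_lt(max(abs(p2 - c0^2 * p1) / p1), 1e-10)
  a1 <- irasa_aperiodic(x, 250); a2 <- irasa_aperiodic(c0 * x, 250)
  expect_lt(max(abs(a2 - c0^2 * a1) / a1), 1e-10)
  f1 <- fit_aperiodic(a1); f2 <- fit_aperiodic(a2)
  expect_equal(f2["slope"], f1["slope"], tolerance = 1e-10)
  expect_equal(unname(f2["intercept"] - f1["intercept"]), 2 * log10(c0),
               tolerance = 1e-10)
})

test_that("Welch mode averages segments and engages only when possible", {
  set.seed(14)
  x <- rnorm(2000)
  # one-segment request equals the single-window spectrum
  expect_identical(compute_psd(x[1:500], 250, seg_s = 2),
                   compute_psd(x[1:500], 250))
  # averaging shrinks the spread of a white-noise spectrum
  p_one <- compute_psd(x, 250)
  p_avg <- compute_psd(x, 250, seg_s = 2)
  expect_lt(stats::sd(p_avg), stats::sd(p_one))
  expect_error(compute_psd(x, 250, seg_s = 0.1), "at least 64")
})
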