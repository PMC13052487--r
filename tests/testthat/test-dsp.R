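test_that("median filter matches a sort-based oracle and kills spikes", {
  expect_equal(median_filter(rep(3, 50), 10), rep(3, 50))

  x <- numeric(60); x[30] <- 100
  expect_equal(median_filter(x, 10)[30], 0)

  set.seed(5)
  for (w in c(3, 4, 7, 10)) {
    x <- rnorm(100)
    expect_equal(median_filter(x, w), bf_median_filter(x, w))
  }
  expect_error(median_filter(numeric(0), 10), "empty")
})

test_that("clipping replaces out-of-band samples by linear interpolation", {
  x <- c(10, 10.2, 9.9, 10.1)
  expect_equal(clip_interpolate(x, 0.1), x)

  # mu = 10.375, band 1.0375: only the 11.5 falls outside
  expect_equal(clip_interpolate(c(10, 10, 11.5, 10), 0.1), c(10, 10, 10, 10))

  # interior outlier takes the midpoint of its adjacent survivors
  y <- clip_interpolate(c(10, 10.4, 14, 9.8, 10), 0.1)
  expect_equal(y[3], (10.4 + 9.8) / 2)

  # leading outlier takes the nearest surviving value
  z <- clip_interpolate(c(15, 10, 10, 10), 0.2)
  expect_equal(z[1], 10)

  expect_error(clip_interpolate(c(1, 100), 0.1), "all samples clipped")
  expect_error(clip_interpolate(c(-5, 5), 0.1), "zero-mean")
})

test_that("EWMA follows its closed-form recursion", {
  x <- rnorm(20)
  expect_equal(ewma(x, 1), x)
  expect_equal(ewma(rep(2.5, 30), 0.2), rep(2.5, 30))
  step <- c(0, rep(1, 40))
  y <- ewma(step, 0.2)
  n <- 1:40
  expect_equal(y[-1], 1 - 0.8^n, tolerance = 1e-12)
  expect_error(ewma(x, 0), "alpha")
  expect_error(ewma(x, 1.2), "alpha")
})

test_that("Chebyshev-II low-pass preserves the passband and cuts the stopband", {
  fs <- 40
  t <- seq(0, 40, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))

  dc <- cheby2_lowpass(rep(2, length(t)), fs, stop_hz = 10)
  expect_lt(max(abs(dc - 2)) / 2, 0.001)

  tone1 <- sin(2 * pi * 1 * t)
  out1 <- cheby2_lowpass(tone1, fs, stop_hz = 10)
  expect_lt(abs(sqrt(mean(out1[mid]^2)) / sqrt(mean(tone1[mid]^2)) - 1), 0.02)

  tone15 <- sin(2 * pi * 15 * t)
  out15 <- cheby2_lowpass(tone15, fs, stop_hz = 10, atten_db = 40)
  expect_lt(sqrt(mean(out15[mid]^2)) / sqrt(mean(tone15[mid]^2)), 10^(-40 / 20))

  expect_error(cheby2_lowpass(tone1, fs, stop_hz = 30), "fs/2")
})

test_that("hard spectral masking passes, zeroes and is idempotent", {
  fs <- 40
  t <- (0:399) / fs
  tone2 <- sin(2 * pi * 2 * t)                 # integer number of periods
  out <- extract_band(tone2, fs, c(0.75, 4))
  expect_lt(max(abs(out - tone2)), 1e-6)

  expect_equal(extract_band(rep(7, 400), fs, c(0.75, 4)), rep(0, 400))

  tone5 <- sin(2 * pi * 5 * t)
  expect_lt(max(abs(extract_band(tone5, fs, c(0.75, 4)))), 1e-10)

  set.seed(2)
  x <- rnorm(400)
  once <- extract_band(x, fs, c(0.75, 4))
  expect_lt(max(abs(extract_band(once, fs, c(0.75, 4)) - once)) /
              max(abs(once)), 1e-10)
  expect_error(extract_band(x, fs, c(5, 25)), "fs/2")
})

test_that("band masks are disjoint and energies bounded by Parseval", {
  fs <- 40
  set.seed(3)
  x <- 5 + rnorm(400)
  ac <- extract_band(x, fs, c(0.75, 4))
  dc <- extract_band(x, fs, c(0, 0.5))
  hc <- extract_band(x, fs, c(6, fs / 2))
  # pairwise disjoint bands: the extractions are mutually orthogonal
  expect_lt(abs(sum(ac * dc)), 1e-8)
  expect_lt(abs(sum(ac * hc)), 1e-8)
  expect_lt(abs(sum(dc * hc)), 1e-8)
  expect_lte(sum(ac^2) + sum(dc^2) + sum(hc^2), sum(x^2) * (1 + 1e-12))
})

test_that("periodic moving average preserves periodic signals, averages noise", {
  per <- rep(c(0, 2, 5, 3, 1), 40)
  expect_equal(periodic_moving_average(per, 5, K = 3), per)
  expect_equal(periodic_moving_average(per + 0.3, 5, K = 1), per + 0.3)
  expect_error(periodic_moving_average(per[1:8], 5), "two periods")

  set.seed(11)
  worse <- 0
  for (i in 1:200) {
    noisy <- per + rnorm(length(per), 0, 0.5)
    sm <- periodic_moving_average(noisy, 5, K = 3)
    worse <- worse + (mean((sm - per)^2) >= mean((noisy - per)^2))
  }
  expect_lt(worse / 200, 0.05)
})

test_that("autocorrelation period estimation finds the cardiac lag", {
  fs <- 40
  t <- (0:599) / fs
  expect_equal(estimate_period(sin(2 * pi * 1 * t), fs), 40L)

  beat <- pulse_waveform((t * 1.8) %% 1)
  expect_lte(abs(estimate_period(beat, fs) - round(40 / 1.8)), 1)

  set.seed(4)
  na_rate <- mean(vapply(1:50, function(i)
    is.na(estimate_period(rnorm(400), fs)), logical(1)))
  expect_gte(na_rate, 0.9)
  expect_error(estimate_period(rnorm(50), fs), "4 s")
})

test_that("window decomposition recovers tone and baseline magnitudes", {
  fs <- 40
  t <- (0:399) / fs
  m <- 1; a <- 0.01
  x <- m + a * sin(2 * pi * 1.2 * t)
  w <- analysis_window(0, 10, x, x, fs)
  d <- decompose_window(w)
  expect_lt(abs(d$red$dc_mean - m) / m, 0.01)
  expect_lt(abs(d$red$ac_rms - a / sqrt(2)) / (a / sqrt(2)), 0.05)
  expect_lt(d$red$hc_rms, 1e-6 * a)

  set.seed(6)
  hf <- extract_band(rnorm(400), fs, c(7, 12))
  wh <- analysis_window(0, 10, 1 + hf, 1 + hf, fs)
  dh <- decompose_window(wh)
  expect_lt(dh$red$ac_rms, 0.05 * dh$red$hc_rms)
  expect_gt(dh$red$hc_rms, 0)

  wc <- analysis_window(0, 10, rep(3, 400), rep(3, 400), fs)
  dc <- decompose_window(wc)
  expect_equal(dc$red$ac_rms, 0)
  expect_equal(dc$red$dc_mean, 3)
})

test_that("the STFT pipeline windows correctly and stays linear", {
  fs <- 40
  t <- (0:(600 * fs - 1)) / fs
  x <- 10 + 0.05 * sin(2 * pi * 1.5 * t) + 0.5 * sin(2 * pi * 0.3 * t)
  rec <- structure(list(fs_hz = fs, t = t, red = x, nir = x, meta = list()),
                   class = "ppg_record")
  stft <- stft_pipeline(rec, window_s = 10, hop_s = 5)
  expect_equal(length(stft$windows), 119)     # floor((600-10)/5)+1

  non <- stft_pipeline(rec, window_s = 10, hop_s = 10)
  expect_equal(length(non$windows), 60)       # floor(600/10)

  rec2 <- rec; rec2$red <- 2 * rec2$red; rec2$nir <- 2 * rec2$nir
  s1 <- stft_pipeline(rec, window_s = 10, hop_s = 60)
  s2 <- stft_pipeline(rec2, window_s = 10, hop_s = 60)
  for (i in seq_along(s1$windows)) {
    expect_equal(s2$windows[[i]]$red$ac_rms, 2 * s1$windows[[i]]$red$ac_rms,
                 tolerance = 1e-6)
    expect_equal(s2$windows[[i]]$red$dc_mean, 2 * s1$windows[[i]]$red$dc_mean,
                 tolerance = 1e-6)
  }
  short <- structure(list(fs_hz = fs, t = t[1:100], red = x[1:100],
                          nir = x[1:100], meta = list()), class = "ppg_record")
  expect_error(stft_pipeline(short, window_s = 10), "shorter")
})

test_that("pipeline DC tracks the generator's analytic baseline within 2%", {
  rec <- noiseless_record(seed = 2, duration_s = 120)
  stft <- stft_pipeline(rec)
  gains <- rec$meta$gains$red
  prof <- make_deox_profile(120)
  for (i in seq_along(stft$windows)) {
    d <- stft$windows[[i]]
    s <- profile_sao2(prof, d$time_s) / 100
    baseline <- gains$S_base - rec$meta$c0 * (s * gains$K_O + (1 - s) * gains$K_D)
    expect_lt(abs(d$red$dc_mean - baseline) / baseline, 0.02)
  }
})
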