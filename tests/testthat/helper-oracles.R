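# Brute-force oracles, independent of the implementation paths they check.

bf_median_filter <- function(x, w) {
  n <- length(x)
  offs <- (-floor(w / 2)):(ceiling(w / 2) - 1)
  vapply(seq_len(n), function(i) {
    idx <- i + offs
    idx <- idx[idx >= 1 & idx <= n]
    stats::median(x[idx])
  }, numeric(1))
}

bf_skewness <- function(x) {
  n <- length(x); mu <- sum(x) / n
  s <- sqrt(sum((x - mu)^2) / (n - 1))
  acc <- 0
  for (xi in x) acc <- acc + (xi - mu)^3
  acc / ((n - 1) * s^3)
}

bf_kurtosis <- function(x) {
  n <- length(x); mu <- sum(x) / n
  s <- sqrt(sum((x - mu)^2) / (n - 1))
  acc <- 0
  for (xi in x) acc <- acc + (xi - mu)^4
  acc / ((n - 1) * s^4)
}

bf_autocorrelation <- function(x, k) {
  n <- length(x); mu <- mean(x)
  num <- 0
  for (t in (k + 1):n) num <- num + (x[t] - mu) * (x[t - k] - mu)
  num / sum((x - mu)^2)
}

bf_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]  # normal equations
}

# Small chromophore set on a tiny custom grid for hand-computable cases.
toy_grid <- function() wavelength_grid(500, 502, 1)
toy_spectrum <- function(name, eps) chromophore_spectrum(name, toy_grid(), eps)

# A short paired trial for pipeline tests.
quick_trial <- function(seed = 7, duration_s = 120, ...) {
  make_paired_trial(seed, duration_s = duration_s, ...)
}

# Clean synthetic record with every stochastic component switched off: the
# analytic baseline is then exact.
noiseless_record <- function(seed = 1, duration_s = 60, melanin_units = 1,
                             pulse_amp = 0.3) {
  profile <- make_deox_profile(duration_s)
  synthesize_ppg(profile, melanin_units, seed = seed,
                 noise_levels = c(white = 0, hf = 0),
                 pulse_amp = pulse_amp, site_amp_sdlog = 0,
                 gain_drift_sd = 0, sensor_drift_sd = 0)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
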