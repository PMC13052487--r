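#' Pulsatility index
#'
#' `(max(x) - min(x)) / mean(x)`, the ratio of pulsatile to static signal,
#' roughly AC/DC. Undefined (`NA`) for zero-mean input; callers treat `NA`
#' metrics as failures rather than errors.
#'
#' @param x Numeric series.
#' @export
pulsatility_index <- function(x) {
  mu <- mean(x)
  if (mu == 0) return(NA_real_)
  (max(x) - min(x)) / mu
}

#' Welch power spectral density
#'
#' Hann-tapered segments (default 4 s) with 50% overlap, averaged
#' periodograms, one-sided.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate.
#' @param seg_s Segment length in seconds.
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` and `psd`.
#' @export
welch_psd <- function(x, fs_hz, seg_s = 4, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seg_s * fs_hz))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  scale <- sum(win^2) * fs_hz
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  list(freq = (seq_len(nf) - 1) * fs_hz / nseg, psd = psd)
}

#' Relative power spectral density
#'
#' Fraction of Welch power in the cardiac band (0.75--4 Hz) relative to the
#' 0--8 Hz total; the frequency-domain analog of the pulsatility index.
#'
#' @param x Numeric series (at least one Welch segment).
#' @param fs_hz Sampling rate.
#' @param band Cardiac band in Hz.
#' @param total_band Reference band in Hz.
#' @export
relative_psd <- function(x, fs_hz, band = c(0.75, 4), total_band = c(0, 8)) {
  W <- welch_psd(x, fs_hz)
  tot <- sum(W$psd[W$freq >= total_band[1] & W$freq <= total_band[2]])
  if (tot == 0) return(NA_real_)
  sum(W$psd[W$freq >= band[1] & W$freq <= band[2]]) / tot
}

#' Sample skewness, (N-1)-denominator convention
#'
#' `sum((x - mu)^3) / ((N - 1) * sd^3)` with the empirical mean and
#' (N-1)-denominator standard deviation.
#'
#' @param x Numeric series, `N >= 3`, nonzero spread.
#' @export
skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  sum((x - mean(x))^3) / ((n - 1) * s^3)
}

#' Sample kurtosis (non-excess), (N-1)-denominator convention
#'
#' `sum((x - mu)^4) / ((N - 1) * sd^4)`.
#'
#' @param x Numeric series, `N >= 4`, nonzero spread.
#' @export
kurtosis <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  sum((x - mean(x))^4) / ((n - 1) * s^4)
}

# One-sided magnitude spectrum above a frequency floor; the sub-0.3 Hz bins
# (and in particular the DC peak) would otherwise dominate the spectral
# moments.
magnitude_spectrum <- function(x, fs_hz, min_hz = 0.3) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  keep <- f > min_hz & f <= fs_hz / 2
  Mod(stats::fft(x))[keep]
}

#' Normalized autocorrelation at a lag
#'
#' `sum_t (y_t - mu)(y_{t-k} - mu) / sum_t (y_t - mu)^2`,
#' overlapping-sample convention (`k = 0` gives 1).
#'
#' @param x Numeric series.
#' @param k Lag in samples, `0 <= k < length(x)`.
#' @export
autocorrelation <- function(x, k) {
  n <- length(x)
  if (k < 0 || k >= n) stop("lag out of range", call. = FALSE)
  y <- x - mean(x)
  den <- sum(y^2)
  if (den == 0) return(NA_real_)
  if (k == 0) return(1)
  sum(y[(k + 1):n] * y[1:(n - k)]) / den
}

#' Cardiac-lag autocorrelation quality index
#'
#' Maximum normalized autocorrelation over lags in the cardiac range
#' (`fs/4` to `fs/0.75` samples), the scalar thresholded by the
#' autocorrelation quality gate.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate.
#' @export
cardiac_autocorr <- function(x, fs_hz) {
  n <- length(x)
  lo <- max(2L, as.integer(ceiling(fs_hz / 4)))
  hi <- min(n - 1L, as.integer(floor(fs_hz / 0.75)))
  rho <- autocorr_lags(x, lo:hi)
  if (all(!is.finite(rho))) return(NA_real_)
  max(rho, na.rm = TRUE)
}

#' Signal-quality exclusion thresholds
#'
#' The printed defaults: a window fails if PI < 5e-5, rPSD < 5e-9, spectral
#' kurtosis < 30, spectral skewness < 4, or cardiac autocorrelation < 0.4.
#' Note the rPSD threshold is reproduced as printed even though rPSD is a
#' ratio in `[0, 1]` (so 5e-9 essentially never triggers); it is
#' configurable here.
#'
#' @param pi_min,rpsd_min,kurt_spec_min,skew_spec_min,autocorr_min Metric
#'   floors.
#' @export
sqi_thresholds <- function(pi_min = 5e-5, rpsd_min = 5e-9, kurt_spec_min = 30,
                           skew_spec_min = 4, autocorr_min = 0.4) {
  th <- list(pi_min = pi_min, rpsd_min = rpsd_min,
             kurt_spec_min = kurt_spec_min, skew_spec_min = skew_spec_min,
             autocorr_min = autocorr_min)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(th, class = "sqi_thresholds")
}

sqi_channel <- function(x, fs, th) {
  mag <- magnitude_spectrum(x, fs)
  vals <- c(pi = pulsatility_index(x),
            rpsd = relative_psd(x, fs),
            skew_time = skewness(x),
            kurt_time = kurtosis(x),
            skew_spec = skewness(mag),
            kurt_spec = kurtosis(mag),
            autocorr = cardiac_autocorr(x, fs))
  ok <- function(v, m) is.finite(v) && v >= m
  passed <- c(pi = ok(vals[["pi"]], th$pi_min),
              rpsd = ok(vals[["rpsd"]], th$rpsd_min),
              kurt_spec = ok(vals[["kurt_spec"]], th$kurt_spec_min),
              skew_spec = ok(vals[["skew_spec"]], th$skew_spec_min),
              autocorr = ok(vals[["autocorr"]], th$autocorr_min))
  list(values = vals, passed = passed, channel_pass = all(passed))
}

#' Evaluate the signal-quality indices of an analysis window
#'
#' Computes all five thresholded metrics (PI, rPSD, spectral kurtosis,
#' spectral skewness, cardiac-lag autocorrelation) plus the unthresholded
#' time-domain skewness/kurtosis, per channel. A channel fails when any
#' thresholded metric falls below its floor (undefined metrics count as
#' failures); the window is admissible only when both channels pass.
#'
#' @param w An [analysis_window()] (or `"component_decomposition"`, in which
#'   case the windowed input series are used).
#' @param thresholds An [sqi_thresholds()] object.
#' @return Object of class `"sqi_report"`.
#' @export
evaluate_window <- function(w, thresholds = sqi_thresholds()) {
  if (inherits(w, "component_decomposition")) {
    red <- w$window$red; nir <- w$window$nir; fs <- w$fs_hz
  } else {
    red <- w$red; nir <- w$nir; fs <- w$fs_hz
  }
  r <- sqi_channel(red, fs, thresholds)
  n <- sqi_channel(nir, fs, thresholds)
  structure(list(red = r, nir = n,
                 admissible = r$channel_pass && n$channel_pass),
            class = "sqi_report")
}

#' @export
print.sqi_report <- function(x, ...) {
  cat("<sqi_report>", if (x$admissible) "admissible" else "REJECTED", "\n")
  m <- rbind(red = x$red$values, nir = x$nir$values)
  print(round(m, 4))
  invisible(x)
}

#' Signal-quality table for a windowed record
#'
#' @param stft A `"ppg_stft"` object.
#' @param thresholds An [sqi_thresholds()] object.
#' @return `data.frame`, one row per window: metric values per channel and
#'   the admissibility flag.
#' @export
evaluate_stft <- function(stft, thresholds = sqi_thresholds()) {
  vals <- vapply(stft$windows, function(d) {
    rep <- evaluate_window(d, thresholds)
    c(time_s = d$time_s,
      stats::setNames(rep$red$values, paste0("red_", names(rep$red$values))),
      stats::setNames(rep$nir$values, paste0("nir_", names(rep$nir$values))),
      red_pass = rep$red$channel_pass,
      nir_pass = rep$nir$channel_pass,
      admissible = rep$admissible)
  }, numeric(18))
  out <- as.data.frame(t(vals))
  out$red_pass <- out$red_pass > 0
  out$nir_pass <- out$nir_pass > 0
  out$admissible <- out$admissible > 0
  out
}
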