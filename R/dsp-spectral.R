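#' Hard spectral band extraction
#'
#' FFT, zero every bin whose absolute frequency lies outside the half-open
#' band `[lo, hi)` (conjugate-symmetrically, no tapering), inverse FFT.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate.
#' @param band `c(lo_hz, hi_hz)` with `0 <= lo < hi <= fs/2`.
#' @export
extract_band <- function(x, fs_hz, band) {
  lo <- band[1]; hi <- band[2]
  if (lo < 0 || hi > fs_hz / 2 || lo >= hi)
    stop("band must satisfy 0 <= lo < hi <= fs/2", call. = FALSE)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  fa <- pmin(f, fs_hz - f)            # absolute frequency of each bin
  keep <- fa >= lo & fa < hi
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Periodic moving average
#'
#' Each sample is replaced by the mean of the available samples at the same
#' phase in `K` neighboring periods (centered), exploiting the
#' quasi-periodicity of the PPG waveform.
#'
#' @param x Numeric series, at least two periods long.
#' @param period_samples Period in samples (>= 2).
#' @param K Number of periods averaged (centered; `K = 1` is the identity).
#' @export
periodic_moving_average <- function(x, period_samples, K = 3) {
  n <- length(x)
  stopifnot(period_samples >= 2, K >= 1)
  if (n < 2 * period_samples)
    stop("series shorter than two periods", call. = FALSE)
  if (K == 1) return(x)
  offs <- seq.int(-floor(K / 2), length.out = K)
  acc <- numeric(n)
  cnt <- numeric(n)
  i <- seq_len(n)
  for (o in offs) {
    j <- i + o * period_samples
    ok <- j >= 1 & j <= n
    acc[ok] <- acc[ok] + x[j[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  acc / cnt
}

#' Estimate the cardiac period by autocorrelation
#'
#' Returns the lag in the cardiac range (`fs/4` to `fs/0.75` samples, i.e.
#' 4 Hz down to 0.75 Hz) maximizing the normalized autocorrelation, provided
#' that maximum is a positive peak; returns `NA` for aperiodic input
#' (callers treat such windows as low quality).
#'
#' @param x Numeric series, at least 4 s of samples.
#' @param fs_hz Sampling rate.
#' @param min_peak Minimum autocorrelation for an acceptable peak.
#' @export
estimate_period <- function(x, fs_hz, min_peak = 0.2) {
  n <- length(x)
  if (n < 4 * fs_hz) stop("need at least 4 s of samples", call. = FALSE)
  lo <- max(2L, as.integer(ceiling(fs_hz / 4)))
  hi <- min(n - 1L, as.integer(floor(fs_hz / 0.75)))
  rho <- autocorr_lags(x, lo:hi)
  k <- which.max(rho)
  if (!is.finite(rho[k]) || rho[k] < min_peak) return(NA_integer_)
  as.integer(lo + k - 1L)
}

# Normalized autocorrelation over a set of lags (overlapping-sample
# convention), computed via FFT.
autocorr_lags <- function(x, lags) {
  n <- length(x)
  y <- x - mean(x)
  den <- sum(y^2)
  if (den == 0) return(rep(NA_real_, length(lags)))
  m <- stats::nextn(2 * n, 2)
  Y <- stats::fft(c(y, numeric(m - n)))
  ac <- Re(stats::fft(Mod(Y)^2, inverse = TRUE)) / m
  ac[lags + 1] / den
}

#' Analysis window
#'
#' A time slice of both channels, the unit of decomposition and
#' quality assessment. At least 4 s of samples.
#'
#' @param t1,t2 Start and end time in seconds (`t2 > t1`).
#' @param red,nir Sample slices, equal length.
#' @param fs_hz Sampling rate.
#' @export
analysis_window <- function(t1, t2, red, nir, fs_hz) {
  stopifnot(t2 > t1, length(red) == length(nir))
  if (length(red) < 4 * fs_hz)
    stop("analysis window must span at least 4 s", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, red = red, nir = nir, fs_hz = fs_hz),
            class = "analysis_window")
}

decompose_channel <- function(x, fs, ac_band = c(0.75, 4), dc_hi = 0.5,
                              hc_lo = 6, dc_ma_s = 5, pma_K = 3) {
  ac0 <- extract_band(x, fs, ac_band)
  p <- tryCatch(estimate_period(ac0, fs), error = function(e) NA_integer_)
  ac <- if (!is.na(p) && length(x) >= 2 * p)
    periodic_moving_average(ac0, p, pma_K) else ac0
  dc <- moving_average(extract_band(x, fs, c(0, dc_hi)), round(dc_ma_s * fs))
  hc <- extract_band(x, fs, c(hc_lo, fs / 2))
  list(ac = ac, dc = dc, hc = hc,
       ac_rms = sqrt(mean(ac^2)), dc_mean = mean(dc),
       hc_rms = sqrt(mean(hc^2)), period_samples = p)
}

#' Decompose an analysis window into AC, DC and HC components
#'
#' Per channel: the pulsatile (AC) component is the 0.75--4 Hz band followed
#' by a periodic moving average, summarized by its RMS; the baseline (DC)
#' component is the sub-0.5 Hz band smoothed with a large (5 s) moving
#' average, summarized by its mean; the high-frequency (HC) component is
#' everything above 6 Hz, summarized by its RMS.
#'
#' @param w An [analysis_window()].
#' @param ac_band,dc_hi,hc_lo Band edges in Hz.
#' @param dc_ma_s Width of the DC moving average in seconds.
#' @param pma_K Periods averaged by the periodic moving average.
#' @return Object of class `"component_decomposition"`: per-channel
#'   component series and scalar magnitudes, plus the windowed input.
#' @export
decompose_window <- function(w, ac_band = c(0.75, 4), dc_hi = 0.5, hc_lo = 6,
                             dc_ma_s = 5, pma_K = 3) {
  out <- list(
    red = decompose_channel(w$red, w$fs_hz, ac_band, dc_hi, hc_lo, dc_ma_s, pma_K),
    nir = decompose_channel(w$nir, w$fs_hz, ac_band, dc_hi, hc_lo, dc_ma_s, pma_K),
    window = list(red = w$red, nir = w$nir),
    fs_hz = w$fs_hz, t1 = w$t1, t2 = w$t2,
    time_s = (w$t1 + w$t2) / 2)
  class(out) <- "component_decomposition"
  out
}

#' Full filtering chain and windowed decomposition (STFT pipeline)
#'
#' Applies, once per channel: running median (10 samples), outlier clipping
#' against the global mean (10%), exponentially weighted moving average,
#' and a zero-phase fourth-order Chebyshev-II low-pass. The filtered record
#' is then cut into overlapping analysis windows, each decomposed with
#' [decompose_window()] -- in effect a short-time Fourier analysis of the
#' record.
#'
#' @param record A `"ppg_record"`.
#' @param window_s Window length in seconds (default 10).
#' @param hop_s Hop between window starts in seconds (default 5).
#' @param pre_filter List of chain parameters: `median_w`, `clip_frac`,
#'   `ewma_alpha`, `cheby_order`, `cheby_stop_hz`, `cheby_atten_db`.
#'   Set an entry to `NULL` to skip that stage.
#' @param ... Passed to [decompose_window()].
#' @return Object of class `"ppg_stft"`: list of decompositions plus the
#'   filtered channels.
#' @export
stft_pipeline <- function(record, window_s = 10, hop_s = 5,
                          pre_filter = list(median_w = 10, clip_frac = 0.10,
                                            ewma_alpha = 0.2, cheby_order = 4,
                                            cheby_stop_hz = 10,
                                            cheby_atten_db = 40), ...) {
  fs <- record$fs_hz
  n <- length(record$t)
  wlen <- round(window_s * fs)
  if (n < wlen) stop("record shorter than one analysis window", call. = FALSE)
  chain <- function(x) {
    if (!is.null(pre_filter$median_w)) x <- median_filter(x, pre_filter$median_w)
    if (!is.null(pre_filter$clip_frac)) x <- clip_interpolate(x, pre_filter$clip_frac)
    if (!is.null(pre_filter$ewma_alpha)) x <- ewma(x, pre_filter$ewma_alpha)
    if (!is.null(pre_filter$cheby_stop_hz))
      x <- cheby2_lowpass(x, fs, pre_filter$cheby_order %||% 4,
                          pre_filter$cheby_stop_hz,
                          pre_filter$cheby_atten_db %||% 40)
    x
  }
  red <- chain(record$red)
  nir <- chain(record$nir)
  duration <- n / fs
  starts <- seq(0, duration - window_s, by = hop_s)
  wins <- lapply(starts, function(s0) {
    i0 <- round(s0 * fs) + 1
    idx <- i0:(i0 + wlen - 1)
    w <- analysis_window(s0, s0 + window_s, red[idx], nir[idx], fs)
    decompose_window(w, ...)
  })
  structure(list(windows = wins, window_starts = starts, window_s = window_s,
                 hop_s = hop_s, fs_hz = fs,
                 filtered = list(red = red, nir = nir), t = record$t,
                 meta = record$meta),
            class = "ppg_stft")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ppg_stft <- function(x, ...) {
  cat(sprintf("<ppg_stft> %d windows of %.3g s (hop %.3g s) @ %.1f Hz\n",
              length(x$windows), x$window_s, x$hop_s, x$fs_hz))
  invisible(x)
}
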