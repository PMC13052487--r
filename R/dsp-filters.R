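#' Centered running median filter
#'
#' Each output sample is the median of the `w`-sample neighborhood centered
#' on it (for even `w`, offsets `-w/2 .. w/2 - 1`); windows shrink at the
#' edges rather than padding with fabricated data.
#'
#' @param x Numeric series.
#' @param w Window size in samples (default 10).
#' @export
median_filter <- function(x, w = 10) {
  n <- length(x)
  if (n == 0) stop("empty input", call. = FALSE)
  stopifnot(w >= 1)
  if (w == 1 || n == 1) return(x)
  w <- min(w, n)
  offs <- (-floor(w / 2)):(ceiling(w / 2) - 1)
  lo <- 1 - min(offs)
  hi <- n - max(offs)
  out <- numeric(n)
  if (hi >= lo) {
    # interior: column matrix of shifted copies, sorted by a vectorized
    # bubble network across columns (w is small), then the median picked out
    m <- vapply(offs, function(o) x[(lo + o):(hi + o)], numeric(hi - lo + 1))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    for (i in seq_len(w - 1)) {
      for (j in seq_len(w - i)) {
        a <- pmin(m[, j], m[, j + 1])
        m[, j + 1] <- pmax(m[, j], m[, j + 1])
        m[, j] <- a
      }
    }
    mid <- (w + 1) / 2
    out[lo:hi] <- if (w %% 2 == 1) m[, mid] else (m[, w / 2] + m[, w / 2 + 1]) / 2
  }
  for (i in seq_len(n)) {
    if (i >= lo && i <= hi) next
    idx <- pmax(1, pmin(n, i + offs))
    idx <- idx[i + offs >= 1 & i + offs <= n]
    out[i] <- stats::median(x[idx])
  }
  out
}

#' Clip outliers against the global mean and interpolate
#'
#' Samples deviating from the global mean by more than `frac * |mean|` are
#' replaced by linear interpolation between the nearest surviving neighbors;
#' leading/trailing outliers take the nearest surviving value.
#'
#' @param x Numeric series of length at least 2, nonzero mean.
#' @param frac Relative deviation threshold (default 0.10).
#' @export
clip_interpolate <- function(x, frac = 0.10) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  mu <- mean(x)
  if (mu == 0) stop("zero-mean series: relative clipping undefined", call. = FALSE)
  bad <- abs(x - mu) > frac * abs(mu)
  if (!any(bad)) return(x)
  if (all(bad)) stop("all samples clipped: uninterpretable record", call. = FALSE)
  idx <- seq_len(n)
  repl <- stats::approx(idx[!bad], x[!bad], xout = idx[bad], rule = 2)$y
  x[bad] <- repl
  x
}

#' Exponentially weighted moving average
#'
#' `y[1] = x[1]`, `y[n] = alpha*x[n] + (1-alpha)*y[n-1]`.
#'
#' @param x Numeric series.
#' @param alpha Smoothing weight in `(0, 1]`.
#' @export
ewma <- function(x, alpha = 0.2) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  if (alpha == 1) return(x)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' Zero-phase Chebyshev type-II low-pass filter
#'
#' Fourth-order Chebyshev-II design applied forward-backward (zero phase).
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate.
#' @param order Filter order (default 4).
#' @param stop_hz Stopband edge in Hz, inside `(0, fs/2)`.
#' @param atten_db Stopband attenuation in dB.
#' @export
cheby2_lowpass <- function(x, fs_hz, order = 4, stop_hz = 10, atten_db = 40) {
  if (stop_hz <= 0 || stop_hz >= fs_hz / 2)
    stop("stopband edge must lie in (0, fs/2)", call. = FALSE)
  flt <- signal::cheby2(order, atten_db, stop_hz / (fs_hz / 2), type = "low")
  if (any(!is.finite(c(flt$b, flt$a))))
    stop("unstable filter design", call. = FALSE)
  # odd-reflection padding suppresses the forward-backward edge transients
  n <- length(x)
  npad <- min(n - 1, max(round(fs_hz), 3 * (order + 1)))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(flt, c(head_pad, x, tail_pad)))
  y[(npad + 1):(npad + n)]
}

#' Centered moving average with shrinking edge windows
#'
#' @param x Numeric series.
#' @param w Window size in samples.
#' @export
moving_average <- function(x, w) {
  n <- length(x)
  stopifnot(n >= 1, w >= 1)
  offs <- (-floor(w / 2)):(ceiling(w / 2) - 1)
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) + min(offs))
  hi <- pmin(n, seq_len(n) + max(offs))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
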