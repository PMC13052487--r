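#' Modulation-ratio metrics of one analysis window
#'
#' Time domain (default): the AC magnitude per channel is the RMS of the
#' decomposed pulsatile series (or its max-min, by `ac_estimator`) and the
#' DC magnitude is the windowed baseline mean. Frequency domain: AC and DC
#' magnitudes are the square roots of the window's spectral power in the
#' cardiac band (0.75--4 Hz) and below 0.5 Hz (including the zero-frequency
#' bin). The AC ratio is red/NIR, the DC ratio NIR/red, and the modulation
#' ratio their product; per-channel pulsatility indices are AC/DC.
#'
#' @param d A `"component_decomposition"`.
#' @param domain `"time"` or `"frequency"`.
#' @param ac_estimator `"rms"` (default) or `"maxmin"` for the time-domain
#'   AC magnitude.
#' @return One-row `data.frame`: `time_s`, `r`, `rac`, `rdc`, `pi_red`,
#'   `pi_nir`, `ac_red`, `ac_nir`, `dc_red`, `dc_nir`, `domain`.
#' @export
window_metrics <- function(d, domain = c("time", "frequency"),
                           ac_estimator = c("rms", "maxmin")) {
  domain <- match.arg(domain)
  ac_estimator <- match.arg(ac_estimator)
  v <- window_metrics_values(d, domain, ac_estimator)
  out <- as.data.frame(as.list(v))
  out$domain <- domain
  out
}

# numeric core of window_metrics, one named vector per window
window_metrics_values <- function(d, domain, ac_estimator) {
  amp <- function(ch) {
    if (domain == "time") {
      ac <- if (ac_estimator == "rms") d[[ch]]$ac_rms
            else max(d[[ch]]$ac) - min(d[[ch]]$ac)
      c(ac = ac, dc = d[[ch]]$dc_mean)
    } else {
      x <- d$window[[ch]]
      n <- length(x)
      f <- (seq_len(n) - 1) * d$fs_hz / n
      fa <- pmin(f, d$fs_hz - f)
      P <- Mod(stats::fft(x))^2 / n^2
      c(ac = sqrt(sum(P[fa >= 0.75 & fa < 4])),
        dc = sqrt(sum(P[fa < 0.5])))
    }
  }
  r <- amp("red"); n <- amp("nir")
  if (!is.finite(n[["ac"]]) || n[["ac"]] == 0 ||
      r[["dc"]] <= 0 || n[["dc"]] <= 0) {
    return(c(time_s = d$time_s, r = NA_real_, rac = NA_real_,
             rdc = NA_real_, pi_red = NA_real_, pi_nir = NA_real_,
             ac_red = r[["ac"]], ac_nir = n[["ac"]],
             dc_red = r[["dc"]], dc_nir = n[["dc"]]))
  }
  rac <- r[["ac"]] / n[["ac"]]
  rdc <- n[["dc"]] / r[["dc"]]
  c(time_s = d$time_s, r = rac * rdc, rac = rac, rdc = rdc,
    pi_red = r[["ac"]] / r[["dc"]], pi_nir = n[["ac"]] / n[["dc"]],
    ac_red = r[["ac"]], ac_nir = n[["ac"]],
    dc_red = r[["dc"]], dc_nir = n[["dc"]])
}

#' Per-window metric table for a windowed record
#'
#' @param stft A `"ppg_stft"`.
#' @param sqi Optional `data.frame` from [evaluate_stft()]; its
#'   `admissible` column becomes the `valid` flag (default all valid).
#' @param domain,ac_estimator Passed to [window_metrics()].
#' @export
stft_metrics <- function(stft, sqi = NULL, domain = "time",
                         ac_estimator = "rms") {
  vals <- vapply(stft$windows, window_metrics_values, numeric(10),
                 domain = domain, ac_estimator = ac_estimator)
  m <- as.data.frame(t(vals))
  m$domain <- domain
  m$valid <- if (is.null(sqi)) !is.na(m$r) else sqi$admissible & !is.na(m$r)
  m
}

#' Match window metrics to ABG reference samples
#'
#' For each ABG sample, the nearest valid window (by center time) within
#' `max_gap_s`; unmatched ABGs are dropped and counted in attribute
#' `"n_dropped"`.
#'
#' @param metrics `data.frame` from [stft_metrics()] (needs `time_s`,
#'   `valid`).
#' @param abg `data.frame` with `time_s`, `sao2`.
#' @param max_gap_s Maximum |window center - ABG time| in seconds.
#' @export
metrics_at_abg <- function(metrics, abg, max_gap_s = 10) {
  ok <- metrics[metrics$valid, , drop = FALSE]
  rows <- lapply(seq_len(nrow(abg)), function(i) {
    if (nrow(ok) == 0) return(NULL)
    gap <- abs(ok$time_s - abg$time_s[i])
    j <- which.min(gap)
    if (gap[j] > max_gap_s) return(NULL)
    cbind(sao2 = abg$sao2[i], abg_time_s = abg$time_s[i], ok[j, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  n_dropped <- nrow(abg) - if (is.null(out)) 0 else nrow(out)
  if (is.null(out))
    out <- cbind(sao2 = numeric(0), abg_time_s = numeric(0), ok[0, ])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-trial linear calibration regression
#'
#' Ordinary least squares of an extracted metric on the reference SaO2.
#' Standard errors, t and p use the trial-level degrees-of-freedom
#' convention df = n - 3 (floored at 1), accounting for the two line
#' parameters plus the animal model.
#'
#' @param sao2 Reference saturations in percent.
#' @param y Metric values (same length).
#' @return Object of class `"oximetry_fit"`.
#' @export
fit_trial_regression <- function(sao2, y) {
  if (is.data.frame(sao2)) { y <- sao2[[2]]; sao2 <- sao2[[1]] }
  n <- length(sao2)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::var(sao2) == 0) stop("degenerate predictor", call. = FALSE)
  sx <- sao2 - mean(sao2)
  slope <- sum(sx * y) / sum(sx^2)
  intercept <- mean(y) - slope * mean(sao2)
  res <- y - intercept - slope * sao2
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- max(n - 3, 1)
  sigma2 <- rss / df
  se_slope <- sqrt(sigma2 / sum(sx^2))
  se_intercept <- sqrt(sigma2 * (1 / n + mean(sao2)^2 / sum(sx^2)))
  t_slope <- slope / se_slope
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(list(slope = slope, intercept = intercept,
                 stderr_slope = se_slope, stderr_intercept = se_intercept,
                 r2 = r2,
                 r2_adjusted = if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2,
                 t_slope = t_slope,
                 p_slope = 2 * stats::pt(-abs(t_slope), df),
                 df = df, n = n, residuals = res,
                 sao2 = sao2, y = y),
            class = "oximetry_fit")
}

#' @export
print.oximetry_fit <- function(x, ...) {
  cat(sprintf("<oximetry_fit> n=%d  slope=%.4g (se %.3g)  intercept=%.4g  R2=%.3f  t=%.3g, df=%d, p=%.3g\n",
              x$n, x$slope, x$stderr_slope, x$intercept, x$r2, x$t_slope,
              x$df, x$p_slope))
  invisible(x)
}

#' @export
coef.oximetry_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Paired t-test on per-trial regression parameters
#'
#' One-sample t-test on within-pair differences (nonpigmented minus
#' pigmented) of a regression field, with the trial-level convention
#' df = n_pairs - 3 (floored at 1) and a two-sided p. With zero-variance
#' differences: all-zero gives t = 0, p = 1; otherwise the t is infinite
#' and p underflows to 0 (flagged via `underflow`).
#'
#' @param pigmented,nonpigmented Equal-length lists of
#'   [fit_trial_regression()] results (or numeric vectors of the field).
#' @param field `"slope"` or `"intercept"`.
#' @export
paired_slope_test <- function(pigmented, nonpigmented, field = c("slope", "intercept")) {
  field <- match.arg(field)
  get <- function(l) if (is.numeric(l)) l else
    vapply(l, function(f) f[[field]], numeric(1))
  a <- get(nonpigmented); b <- get(pigmented)
  if (length(a) != length(b) || length(a) < 2)
    stop("need equal-length paired lists with at least 2 pairs", call. = FALSE)
  d <- a - b
  n <- length(d)
  df <- max(n - 3, 1)
  md <- mean(d)
  s <- stats::sd(d)
  underflow <- FALSE
  if (s == 0) {
    if (md == 0) { t <- 0; p <- 1 } else { t <- Inf * sign(md); p <- 0; underflow <- TRUE }
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(mean_diff = md, t = t, p = p, df = df, n_pairs = n,
                 field = field, underflow = underflow),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("<paired_test> %s: mean diff %.4g, t=%.3g, df=%d, p=%.3g (n=%d pairs)\n",
              x$field, x$mean_diff, x$t, x$df, x$p, x$n_pairs))
  invisible(x)
}

#' Pooled difference regression across trials
#'
#' Pools the nonpigmented-minus-pigmented metric differences at ABG-matched
#' timepoints across trials and regresses the difference on SaO2; the slope
#' t-test (df = n - 3) asks whether the pigmentation gap changes across
#' saturation.
#'
#' @param pairs List with one element per trial, each a `data.frame` with
#'   columns `sao2`, `nonpigmented`, `pigmented` (differences taken
#'   rowwise); or a single such `data.frame`.
#' @return An `"oximetry_fit"` on the pooled differences.
#' @export
difference_regression_test <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  pooled <- do.call(rbind, lapply(pairs, function(p)
    data.frame(sao2 = p$sao2, diff = p$nonpigmented - p$pigmented)))
  pooled <- pooled[stats::complete.cases(pooled), ]
  if (nrow(pooled) < 3) stop("need at least 3 pooled points", call. = FALSE)
  fit_trial_regression(pooled$sao2, pooled$diff)
}

#' Agreement between paired modulation-ratio series
#'
#' Squared Pearson correlation of the time-aligned modulation-ratio series
#' from the two skin sites, before (`r2_all`) and after (`r2_adjusted`)
#' dropping windows that are invalid in either record.
#'
#' @param pigmented_r,nonpigmented_r Equal-length per-window series.
#' @param validity Logical flags (both records admissible); default all.
#' @export
agreement_r2 <- function(pigmented_r, nonpigmented_r,
                         validity = rep(TRUE, length(pigmented_r))) {
  stopifnot(length(pigmented_r) == length(nonpigmented_r),
            length(validity) == length(pigmented_r))
  both <- stats::complete.cases(pigmented_r, nonpigmented_r)
  r2 <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)^2
  }
  keep <- both & validity
  list(r2_all = r2(pigmented_r[both], nonpigmented_r[both]),
       r2_adjusted = r2(pigmented_r[keep], nonpigmented_r[keep]),
       n_all = sum(both), n_adjusted = sum(keep))
}
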