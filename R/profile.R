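#' Deoxygenation profile
#'
#' Smooth monotone SaO2 ramp from `start` to `end` over the trial, a
#' normalized logistic in time with optional small jitter.
#'
#' @param duration_s Trial duration in seconds.
#' @param start,end Saturation endpoints in percent, `end < start`.
#' @param seed Optional seed controlling the jitter realization.
#' @param jitter Standard deviation (percent SaO2) of a smoothed noise term
#'   added to the ramp; 0 (default) gives a strictly nonincreasing profile.
#' @param midpoint,steepness Logistic shape parameters on the normalized
#'   time axis.
#' @return Object of class `"deox_profile"` with per-second `times` and
#'   `sao2`.
#' @export
make_deox_profile <- function(duration_s, start = 100, end = 70, seed = NULL,
                              jitter = 0, midpoint = 0.5, steepness = 0.12) {
  stopifnot(duration_s > 0)
  if (!(end < start) || end < 0 || start > 100)
    stop("need 0 <= end < start <= 100", call. = FALSE)
  times <- seq(0, duration_s, by = 1)
  u <- times / duration_s
  l <- function(z) 1 / (1 + exp(-(z - midpoint) / steepness))
  ramp <- (l(u) - l(0)) / (l(1) - l(0))
  sao2 <- start - (start - end) * ramp
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- stats::filter(stats::rnorm(length(times), 0, jitter),
                           rep(1 / 15, 15), sides = 2)
    noise[is.na(noise)] <- 0
    sao2 <- pmin(start, pmax(end - 2 * jitter, sao2 + as.numeric(noise)))
  }
  structure(list(times = times, sao2 = sao2, start = start, end = end,
                 duration_s = duration_s, jitter = jitter),
            class = "deox_profile")
}

#' Evaluate a deoxygenation profile
#'
#' Linear interpolation of the profile at arbitrary times.
#'
#' @param profile A [make_deox_profile()] object.
#' @param t Times in seconds.
#' @export
profile_sao2 <- function(profile, t) {
  stats::approx(profile$times, profile$sao2, xout = t, rule = 2)$y
}

#' Sample arterial blood gases along a trial
#'
#' Stratified-uniform sampling times over the trial, with the ground-truth
#' saturation read off the profile.
#'
#' @param profile A [make_deox_profile()] object.
#' @param n Number of ABG samples (at least 2; about 10 per deoxygenation
#'   cycle in practice).
#' @param seed Optional seed.
#' @return `data.frame` with columns `time_s`, `sao2`.
#' @export
sample_abg <- function(profile, n = 10, seed = NULL) {
  if (n < 2) stop("need at least 2 ABG samples for a regression", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  T <- profile$duration_s
  edges <- seq(0, T, length.out = n + 1)
  t <- edges[-(n + 1)] + stats::runif(n) * diff(edges)
  data.frame(time_s = t, sao2 = profile_sao2(profile, t))
}
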