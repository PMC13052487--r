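#' PPG-like cardiac pulse waveform
#'
#' Asymmetric beat shape on phase `[0, 1)`: raised-cosine systolic upstroke
#' followed by an exponential diastolic decay. Peak value 1, minimum 0.
#'
#' @param phase Phase within the beat, in `[0, 1)`.
#' @param rise Fraction of the period occupied by the upstroke.
#' @param decay Exponential decay constant in period units.
#' @export
pulse_waveform <- function(phase, rise = 0.15, decay = 0.2) {
  w <- numeric(length(phase))
  up <- phase < rise
  w[up] <- 0.5 * (1 - cos(pi * phase[up] / rise))
  w[!up] <- exp(-(phase[!up] - rise) / decay)
  w
}

# RMS of the zero-mean pulse waveform, used to express noise levels relative
# to the cardiac AC amplitude.
pulse_sd <- function(rise = 0.15, decay = 0.2) {
  ph <- seq(0, 1, length.out = 2001)[-2001]
  stats::sd(pulse_waveform(ph, rise, decay))
}

# Smooth multiplicative drift: cubic spline through independent log-gain
# knots every knot_s seconds, so essentially all its power sits far below
# the cardiac band and it cannot masquerade as pulsatile signal.
slow_drift <- function(n, fs, sigma, knot_s = 20) {
  if (sigma <= 0) return(rep(1, n))
  t <- (seq_len(n) - 1) / fs
  kt <- seq(0, t[n] + knot_s, by = knot_s)
  kv <- stats::rnorm(length(kt), 0, sigma)
  exp(stats::spline(kt, kv, xout = t)$y)
}

# Stationary AR(1) log-gain drift with time constant tau_s, sd sigma.
ar1_drift <- function(n, fs, sigma = 0.08, tau_s = 30) {
  if (sigma <= 0) return(rep(1, n))
  phi <- exp(-1 / (tau_s * fs))
  innov_sd <- sigma * sqrt(1 - phi^2)
  d <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                method = "recursive",
                                init = stats::rnorm(1, 0, sigma)))
  exp(d)
}

#' Synthesize one two-channel PPG record
#'
#' Evaluates the pulsatile forward model at 120 Hz and block-averages every
#' three samples to the 40 Hz output rate. The dermis blood concentration is
#' `c(t) = c0 * (1 + beta_resp * sin(2*pi*rr*t)) + dc * g(t) * pulse(t)`,
#' where `pulse` is a quasi-periodic cardiac waveform (per-beat period
#' jitter +/-3%) and `g` a slow per-channel gain drift; the Hb/HbO2 split
#' follows the deoxygenation profile. White sensor noise and a >6 Hz noise
#' component are added, scaled to the channel's analytic cardiac AC RMS.
#'
#' @param profile A [make_deox_profile()].
#' @param melanin_units Epidermis melanin units of this skin site.
#' @param seed Integer seed; identical seeds give identical records.
#' @param fs_native Native sampling rate before 3-sample averaging (120 Hz).
#' @param hr_hz Heart rate in Hz, within the cardiac band `[0.75, 4]`.
#' @param rr_hz Respiratory rate in Hz, within `[0.25, 0.75]`.
#' @param noise_levels Named vector `c(white=, hf=)` of noise standard
#'   deviations relative to the cardiac AC RMS of each channel.
#' @param total Photon budget; default the shared paired budget.
#' @param c0 Baseline blood concentration (model units).
#' @param pulse_amp Pulsatile blood increment as a fraction of `c0`.
#' @param site_amp_sdlog Log-sd of a per-record perfusion factor multiplying
#'   `pulse_amp` (shared by both channels, so it cancels in channel ratios).
#' @param beta_resp Fractional respiratory modulation of baseline blood.
#' @param gain_drift_sd,gain_drift_tau_s Per-channel slow amplitude drift of
#'   the pulsatile component (sd of log-gain; AR(1) time constant).
#' @param sensor_drift_sd,sensor_drift_knot_s Per-channel slow multiplicative
#'   sensor-gain drift applied to the whole detected intensity (LED/coupling
#'   drift): a smooth spline through log-gain knots every
#'   `sensor_drift_knot_s` seconds. It perturbs the AC and DC ratios
#'   individually but cancels in the modulation ratio and the pulsatility
#'   indices.
#' @param artifacts Optional motion artifacts: `list(n=, amp=, width_s=)`
#'   adds `n` smooth low-frequency transients of `amp` x cardiac AC RMS.
#'   Default none.
#' @param site Site label stored in `meta`.
#' @return Object of class `"ppg_record"`.
#' @export
synthesize_ppg <- function(profile, melanin_units, seed,
                           fs_native = 120, hr_hz = 1.8, rr_hz = 0.4,
                           noise_levels = c(white = 0.2, hf = 0.1),
                           total = NULL, c0 = 1, pulse_amp = 0.3,
                           site_amp_sdlog = 0.6, beta_resp = 0.05,
                           gain_drift_sd = 0.08, gain_drift_tau_s = 30,
                           sensor_drift_sd = 0.001, sensor_drift_knot_s = 60,
                           artifacts = NULL, site = "site") {
  if (hr_hz < 0.75 || hr_hz > 4)
    stop("heart rate outside cardiac band [0.75, 4] Hz", call. = FALSE)
  if (rr_hz < 0.25 || rr_hz > 0.75)
    stop("respiratory rate outside [0.25, 0.75] Hz", call. = FALSE)
  if (is.null(total)) total <- paired_photon_budget()
  set.seed(seed)

  duration <- profile$duration_s
  n_native <- floor(duration * fs_native)
  n_native <- n_native - n_native %% 3
  t <- (seq_len(n_native) - 1) / fs_native
  s <- profile_sao2(profile, t) / 100

  # quasi-periodic beat train
  mean_period <- 1 / hr_hz
  n_beats <- ceiling(duration / (mean_period * 0.97)) + 2
  periods <- mean_period * (1 + 0.03 * stats::runif(n_beats, -1, 1))
  starts <- c(0, cumsum(periods))
  beat <- findInterval(t, starts)
  phase <- (t - starts[beat]) / periods[beat]
  w <- pulse_waveform(phase)

  dc_eff <- pulse_amp * exp(stats::rnorm(1, 0, site_amp_sdlog))
  resp <- 1 + beta_resp * sin(2 * pi * rr_hz * t)

  gains <- list(red = channel_gains(melanin_units, "red", total),
                nir = channel_gains(melanin_units, "nir", total))
  s_bar <- mean(s)
  channels <- list()
  for (ch in c("red", "nir")) {
    gn <- gains[[ch]]
    kappa <- s * gn$K_O + (1 - s) * gn$K_D
    g_drift <- ar1_drift(n_native, fs_native, gain_drift_sd, gain_drift_tau_s)
    conc <- c0 * resp + dc_eff * g_drift * w
    x <- gn$S_base - conc * kappa
    x <- x * slow_drift(n_native, fs_native, sensor_drift_sd,
                        knot_s = sensor_drift_knot_s)
    ac_ref <- dc_eff * pulse_sd() * (s_bar * gn$K_O + (1 - s_bar) * gn$K_D)
    x <- x + stats::rnorm(n_native, 0, noise_levels[["white"]] * ac_ref)
    hf <- extract_band(stats::rnorm(n_native), fs_native, c(6, 14))
    x <- x + hf / stats::sd(hf) * noise_levels[["hf"]] * ac_ref
    if (!is.null(artifacts) && artifacts$n > 0) {
      centers <- stats::runif(artifacts$n, 0, duration)
      for (tc in centers)
        x <- x + artifacts$amp * ac_ref *
          exp(-(t - tc)^2 / (2 * (artifacts$width_s / 2)^2))
    }
    channels[[ch]] <- list(x = x, ac_ref = ac_ref)
  }

  # 3-sample block average to 40 Hz
  dec <- function(v) colMeans(matrix(v, nrow = 3))
  structure(list(
    fs_hz = fs_native / 3,
    t = dec(t),
    red = dec(channels$red$x),
    nir = dec(channels$nir$x),
    meta = list(melanin_units = melanin_units, seed = seed, site = site,
                hr_hz = hr_hz, rr_hz = rr_hz, total = total, c0 = c0,
                delta_c = dc_eff, beta_resp = beta_resp,
                noise_levels = noise_levels,
                gains = gains,
                ac_ref = list(red = channels$red$ac_ref,
                              nir = channels$nir$ac_ref))),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %.1f Hz (%.0f s), melanin %.3g units, site '%s'\n",
              length(x$t), x$fs_hz, length(x$t) / x$fs_hz,
              x$meta$melanin_units, x$meta$site))
  invisible(x)
}

#' Paired pigmented/nonpigmented deoxygenation trial
#'
#' One deoxygenation profile with two simultaneous recordings differing only
#' in melanin units and noise realization, plus shared ABG reference samples.
#'
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param units_dark,units_light Melanin units of the two arms
#'   (`units_dark >= units_light`; equal units give a null trial with no
#'   pigmentation effect, useful as a negative control).
#' @param duration_s Trial duration (desk default 600 s).
#' @param n_abg Number of ABG reference samples.
#' @param total Photon budget shared by both arms; default
#'   [paired_photon_budget()] at the darkest condition.
#' @param ... Further arguments passed to [synthesize_ppg()].
#' @return Object of class `"ppg_trial"` with fields `pigmented`,
#'   `nonpigmented`, `abg`, `profile`.
#' @export
make_paired_trial <- function(seed, units_dark = 5, units_light = 1,
                              duration_s = 600, n_abg = 10, total = NULL, ...) {
  if (units_dark < units_light)
    stop("units_dark must be at least units_light", call. = FALSE)
  if (is.null(total)) total <- paired_photon_budget(units_dark)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1, 3)
  profile <- make_deox_profile(duration_s, seed = seed)
  abg <- sample_abg(profile, n = n_abg, seed = sub[1])
  pig <- synthesize_ppg(profile, units_dark, seed = sub[2], total = total,
                        site = "pigmented", ...)
  non <- synthesize_ppg(profile, units_light, seed = sub[3], total = total,
                        site = "nonpigmented", ...)
  structure(list(pigmented = pig, nonpigmented = non, abg = abg,
                 profile = profile, seed = seed),
            class = "ppg_trial")
}

#' @export
print.ppg_trial <- function(x, ...) {
  cat(sprintf("<ppg_trial> %.0f s, melanin %g vs %g units, %d ABGs, seed %d\n",
              x$profile$duration_s, x$pigmented$meta$melanin_units,
              x$nonpigmented$meta$melanin_units, nrow(x$abg), x$seed))
  invisible(x)
}
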