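#' Default experiment configuration
#'
#' Every tunable parameter of the generator, the filtering chain, the
#' signal-quality thresholds and the analysis, with the package defaults.
#' The structure round-trips losslessly through [write_config()] /
#' [read_config()].
#'
#' @export
default_config <- function() {
  list(
    n_trials = 20,
    duration_s = 600,
    units_dark = 5,
    units_light = 1,
    n_abg = 10,
    generator = list(hr_hz = 1.8, rr_hz = 0.4,
                     noise_white = 0.2, noise_hf = 0.1,
                     pulse_amp = 0.3, site_amp_sdlog = 0.6,
                     beta_resp = 0.05, gain_drift_sd = 0.08,
                     gain_drift_tau_s = 30, sensor_drift_sd = 0.001,
                     sensor_drift_knot_s = 60, c0 = 1),
    dsp = list(window_s = 10, hop_s = 5, median_w = 10, clip_frac = 0.10,
               ewma_alpha = 0.2, cheby_order = 4, cheby_stop_hz = 10,
               cheby_atten_db = 40, dc_ma_s = 5, pma_K = 3),
    sqi = list(pi_min = 5e-5, rpsd_min = 5e-9, kurt_spec_min = 30,
               skew_spec_min = 4, autocorr_min = 0.4),
    analysis = list(domain = "time", ac_estimator = "rms", max_gap_s = 10)
  )
}

validate_config <- function(config) {
  d <- default_config()
  for (nm in names(d)) if (is.null(config[[nm]])) config[[nm]] <- d[[nm]]
  for (nm in c("generator", "dsp", "sqi", "analysis"))
    for (k in names(d[[nm]]))
      if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- d[[nm]][[k]]
  stopifnot(config$n_trials >= 1, config$duration_s > 0,
            config$units_dark >= config$units_light, config$n_abg >= 2,
            config$generator$hr_hz >= 0.75, config$generator$hr_hz <= 4,
            config$generator$rr_hz >= 0.25, config$generator$rr_hz <= 0.75,
            config$dsp$window_s > 0, config$dsp$hop_s > 0,
            config$analysis$domain %in% c("time", "frequency"))
  config
}

#' Read / write a configuration file
#'
#' YAML serialization of the configuration list.
#'
#' @param path File path.
#' @param config Configuration list.
#' @name config_io
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

trial_from_config <- function(seed, config) {
  g <- config$generator
  make_paired_trial(seed,
                    units_dark = config$units_dark,
                    units_light = config$units_light,
                    duration_s = config$duration_s,
                    n_abg = config$n_abg,
                    hr_hz = g$hr_hz, rr_hz = g$rr_hz,
                    noise_levels = c(white = g$noise_white, hf = g$noise_hf),
                    pulse_amp = g$pulse_amp, site_amp_sdlog = g$site_amp_sdlog,
                    beta_resp = g$beta_resp, gain_drift_sd = g$gain_drift_sd,
                    gain_drift_tau_s = g$gain_drift_tau_s,
                    sensor_drift_sd = g$sensor_drift_sd,
                    sensor_drift_knot_s = g$sensor_drift_knot_s, c0 = g$c0)
}

#' Process one record through the DSP + SQI + metrics stages
#'
#' @param record A `"ppg_record"`.
#' @param config Configuration list (see [default_config()]).
#' @return List with the `"ppg_stft"`, the SQI table and the per-window
#'   metric table (with validity flags).
#' @export
process_record <- function(record, config = default_config()) {
  config <- validate_config(config)
  dsp <- config$dsp
  stft <- stft_pipeline(record, window_s = dsp$window_s, hop_s = dsp$hop_s,
                        pre_filter = list(median_w = dsp$median_w,
                                          clip_frac = dsp$clip_frac,
                                          ewma_alpha = dsp$ewma_alpha,
                                          cheby_order = dsp$cheby_order,
                                          cheby_stop_hz = dsp$cheby_stop_hz,
                                          cheby_atten_db = dsp$cheby_atten_db),
                        dc_ma_s = dsp$dc_ma_s, pma_K = dsp$pma_K)
  th <- do.call(sqi_thresholds, config$sqi)
  sqi <- evaluate_stft(stft, th)
  metrics <- stft_metrics(stft, sqi, domain = config$analysis$domain,
                          ac_estimator = config$analysis$ac_estimator)
  list(stft = stft, sqi = sqi, metrics = metrics)
}

.METRICS <- c("r", "rac", "rdc", "pi_red", "pi_nir")

#' Process and analyze one paired trial
#'
#' Runs both arms through [process_record()], matches windows to the shared
#' ABG samples, and fits the per-trial calibration regressions for the
#' modulation ratio, the AC and DC ratios and the per-channel pulsatility
#' indices.
#'
#' @param trial A `"ppg_trial"`.
#' @param config Configuration list.
#' @return List with per-arm processed results, ABG-matched tables, fits
#'   (`fits[[arm]][[metric]]`), and the agreement R-squared.
#' @export
process_trial <- function(trial, config = default_config()) {
  config <- validate_config(config)
  arms <- list(pigmented = process_record(trial$pigmented, config),
               nonpigmented = process_record(trial$nonpigmented, config))
  matched <- lapply(arms, function(a)
    metrics_at_abg(a$metrics, trial$abg, config$analysis$max_gap_s))
  fits <- lapply(matched, function(m) {
    out <- list()
    for (met in .METRICS)
      out[[met]] <- tryCatch(fit_trial_regression(m$sao2, m[[met]]),
                             error = function(e) NULL)
    out
  })
  agree <- agreement_r2(arms$pigmented$metrics$r, arms$nonpigmented$metrics$r,
                        arms$pigmented$metrics$valid & arms$nonpigmented$metrics$valid)
  list(arms = arms, matched = matched, fits = fits, agreement = agree)
}

#' Run a full replicated paired-trial experiment
#'
#' Generates `n_trials` paired pigmented/nonpigmented deoxygenation trials,
#' processes both arms (filtering, windowed decomposition, signal-quality
#' gating), extracts per-window metrics, fits the per-trial regressions
#' against ABG SaO2, and runs the paired slope/intercept tests and the
#' pooled difference regressions. Fully reproducible from `seed`.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return Object of class `"oximetry_experiment"`.
#' @export
run_experiment <- function(config = default_config(), seed = 1,
                           out_dir = NULL) {
  config <- validate_config(config)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, config$n_trials)
  rows <- list(); diffs <- list(); agree <- list(); sqirate <- list()
  fits_all <- list(pigmented = list(), nonpigmented = list())
  for (i in seq_len(config$n_trials)) {
    trial <- trial_from_config(trial_seeds[i], config)
    res <- process_trial(trial, config)
    for (arm in names(res$fits)) {
      for (met in .METRICS) {
        f <- res$fits[[arm]][[met]]
        if (is.null(f)) next
        rows[[length(rows) + 1]] <- data.frame(
          trial = i, arm = arm, metric = met, slope = f$slope,
          intercept = f$intercept, stderr_slope = f$stderr_slope,
          t = f$t_slope, p = f$p_slope, df = f$df, r2 = f$r2, n = f$n)
        fits_all[[arm]][[met]] <- c(fits_all[[arm]][[met]], list(f))
      }
    }
    diffs[[i]] <- lapply(.METRICS, function(met)
      data.frame(sao2 = res$matched$pigmented$sao2[
                   match(res$matched$nonpigmented$abg_time_s,
                         res$matched$pigmented$abg_time_s)],
                 nonpigmented = res$matched$nonpigmented[[met]],
                 pigmented = res$matched$pigmented[[met]][
                   match(res$matched$nonpigmented$abg_time_s,
                         res$matched$pigmented$abg_time_s)]))
    names(diffs[[i]]) <- .METRICS
    agree[[i]] <- res$agreement
    sqirate[[i]] <- c(pigmented = mean(res$arms$pigmented$sqi$admissible),
                      nonpigmented = mean(res$arms$nonpigmented$sqi$admissible))
  }
  trial_fits <- do.call(rbind, rows)

  paired <- list()
  for (met in .METRICS) {
    p <- fits_all$pigmented[[met]]; np <- fits_all$nonpigmented[[met]]
    if (length(p) >= 2 && length(p) == length(np)) {
      paired[[met]] <- list(slope = paired_slope_test(p, np, "slope"),
                            intercept = paired_slope_test(p, np, "intercept"))
    }
  }
  difference <- list()
  for (met in .METRICS) {
    pts <- lapply(diffs, `[[`, met)
    difference[[met]] <- tryCatch(difference_regression_test(pts),
                                  error = function(e) NULL)
  }
  agreement <- list(
    r2_all = vapply(agree, `[[`, numeric(1), "r2_all"),
    r2_adjusted = vapply(agree, `[[`, numeric(1), "r2_adjusted"))

  out <- structure(list(config = config, seed = seed,
                        trial_fits = trial_fits, paired = paired,
                        difference = difference, agreement = agreement,
                        sqi_pass = do.call(rbind, sqirate),
                        n_trials = config$n_trials),
                   class = "oximetry_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$trial_fits, file.path(out_dir, "trial_fits.csv"),
                   row.names = FALSE)
  summ <- summary(x)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    dput(summ, file.path(out_dir, "summary.txt"))
  }
  invisible(out_dir)
}

#' @export
summary.oximetry_experiment <- function(object, ...) {
  sl <- function(met, arm) {
    f <- object$trial_fits
    f$slope[f$metric == met & f$arm == arm]
  }
  paired_p <- lapply(object$paired, function(m)
    list(slope_p = m$slope$p, slope_t = m$slope$t,
         intercept_p = m$intercept$p, intercept_t = m$intercept$t))
  diff_p <- lapply(object$difference, function(f)
    if (is.null(f)) NULL else list(slope = f$slope, t = f$t_slope, p = f$p_slope))
  list(n_trials = object$n_trials, seed = object$seed,
       mean_slope_r_pigmented = mean(sl("r", "pigmented")),
       mean_slope_r_nonpigmented = mean(sl("r", "nonpigmented")),
       frac_trials_attenuated = mean(abs(sl("r", "pigmented")) <
                                       abs(sl("r", "nonpigmented"))),
       paired = paired_p, difference = diff_p,
       mean_r2_all = mean(object$agreement$r2_all, na.rm = TRUE),
       mean_r2_adjusted = mean(object$agreement$r2_adjusted, na.rm = TRUE),
       sqi_pass_rate = colMeans(object$sqi_pass))
}

#' @export
print.oximetry_experiment <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<oximetry_experiment> %d paired trials (seed %d)\n",
              x$n_trials, x$seed))
  cat(sprintf("  mean R~SaO2 slope: pigmented %.4g, nonpigmented %.4g (attenuated in %.0f%% of trials)\n",
              s$mean_slope_r_pigmented, s$mean_slope_r_nonpigmented,
              100 * s$frac_trials_attenuated))
  cat(sprintf("  paired slope test (R): t=%.3g, p=%.3g\n",
              s$paired$r$slope_t, s$paired$r$slope_p))
  for (met in names(s$difference)) {
    d <- s$difference[[met]]
    if (!is.null(d))
      cat(sprintf("  difference regression %-6s slope=%.4g, t=%.3g, p=%.3g\n",
                  paste0(met, ":"), d$slope, d$t, d$p))
  }
  cat(sprintf("  SQI pass rate: pigmented %.2f, nonpigmented %.2f\n",
              s$sqi_pass_rate[["pigmented"]], s$sqi_pass_rate[["nonpigmented"]]))
  invisible(x)
}

#' @export
plot.oximetry_experiment <- function(x, metric = "r", ...) {
  f <- x$trial_fits[x$trial_fits$metric == metric, ]
  graphics::plot(range(70, 100), range(0, max(f$intercept + 70 * f$slope)),
                 type = "n", xlab = "SaO2 (%)", ylab = metric,
                 main = sprintf("Per-trial %s calibration lines", metric), ...)
  for (i in seq_len(nrow(f))) {
    col <- if (f$arm[i] == "pigmented") "sienna4" else "tan2"
    graphics::abline(f$intercept[i], f$slope[i], col = col)
  }
  graphics::legend("topright", legend = c("pigmented", "nonpigmented"),
                   col = c("sienna4", "tan2"), lty = 1, bty = "n")
  invisible(x)
}
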