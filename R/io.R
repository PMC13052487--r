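#' Write / read a PPG record as CSV
#'
#' Columns `t`, `red`, `nir` at full double precision, with scalar metadata
#' (sampling rate, melanin units, site, seed) in commented header lines so a
#' round trip reproduces the record.
#'
#' @param record A `"ppg_record"`.
#' @param path CSV file path.
#' @name record_io
#' @export
write_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- record$meta
  writeLines(sprintf("# fs_hz=%.17g", record$fs_hz), con)
  writeLines(sprintf("# melanin_units=%.17g", meta$melanin_units %||% NA), con)
  writeLines(sprintf("# site=%s", meta$site %||% ""), con)
  writeLines(sprintf("# seed=%d", as.integer(meta$seed %||% NA)), con)
  writeLines("t,red,nir", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", record$t, record$red, record$nir), con)
  invisible(path)
}

#' @rdname record_io
#' @param tol Relative tolerance on timestamp uniformity.
#' @export
read_record <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NA)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  if (!all(c("t", "red", "nir") %in% names(tab)))
    stop("record CSV needs columns t, red, nir", call. = FALSE)
  t <- tab$t
  if (length(t) < 2) stop("record too short", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(abs(dt - stats::median(dt))) > tol * stats::median(dt))
    stop("non-uniform timestamps beyond tolerance", call. = FALSE)
  fs <- as.numeric(getv("fs_hz"))
  if (!is.finite(fs)) fs <- 1 / stats::median(dt)
  structure(list(fs_hz = fs, t = t, red = tab$red, nir = tab$nir,
                 meta = list(melanin_units = as.numeric(getv("melanin_units")),
                             site = getv("site"),
                             seed = suppressWarnings(as.integer(getv("seed"))))),
            class = "ppg_record")
}

#' Write / read a paired trial as a directory of CSV files
#'
#' `samples.csv` holds both records long-form (`t, red, nir, site`),
#' `abg.csv` the reference samples, and `meta.csv` scalar metadata.
#'
#' @param trial A `"ppg_trial"`.
#' @param dir Directory path (created if needed).
#' @name trial_io
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- function(rec, site)
    sprintf("%.17g,%.17g,%.17g,%s", rec$t, rec$red, rec$nir, site)
  writeLines(c("t,red,nir,site",
               rows(trial$pigmented, "pigmented"),
               rows(trial$nonpigmented, "nonpigmented")),
             file.path(dir, "samples.csv"))
  utils::write.csv(trial$abg, file.path(dir, "abg.csv"), row.names = FALSE)
  meta <- data.frame(
    key = c("fs_hz", "units_pigmented", "units_nonpigmented", "seed",
            "duration_s"),
    value = c(trial$pigmented$fs_hz, trial$pigmented$meta$melanin_units,
              trial$nonpigmented$meta$melanin_units, trial$seed,
              trial$profile$duration_s))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname trial_io
#' @export
read_trial <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "samples.csv"))
  abg <- utils::read.csv(file.path(dir, "abg.csv"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  getv <- function(k) as.numeric(meta$value[meta$key == k])
  mk <- function(site, units) {
    s <- samples[samples$site == site, ]
    structure(list(fs_hz = getv("fs_hz"), t = s$t, red = s$red, nir = s$nir,
                   meta = list(melanin_units = units, site = site,
                               seed = as.integer(getv("seed")))),
              class = "ppg_record")
  }
  structure(list(pigmented = mk("pigmented", getv("units_pigmented")),
                 nonpigmented = mk("nonpigmented", getv("units_nonpigmented")),
                 abg = abg, profile = NULL, seed = as.integer(getv("seed"))),
            class = "ppg_trial")
}

#' Write per-window decomposition magnitudes as CSV
#'
#' One row per window and channel: `window_start_s, channel, ac_rms,
#' dc_mean, hc_rms`.
#'
#' @param stft A `"ppg_stft"`.
#' @param path CSV file path.
#' @export
write_decomposition <- function(stft, path) {
  rows <- do.call(rbind, lapply(seq_along(stft$windows), function(i) {
    d <- stft$windows[[i]]
    data.frame(window_start_s = rep(stft$window_starts[i], 2),
               channel = c("red", "nir"),
               ac_rms = c(d$red$ac_rms, d$nir$ac_rms),
               dc_mean = c(d$red$dc_mean, d$nir$dc_mean),
               hc_rms = c(d$red$hc_rms, d$nir$hc_rms))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
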