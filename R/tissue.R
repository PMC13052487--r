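#' Tissue layer
#'
#' One optical layer of the stack: a thickness and the concentrations (model
#' units) of its light-absorbing constituents.
#'
#' @param name Layer label, e.g. `"epidermis"` or `"dermis"`.
#' @param thickness_mm Path length in mm, positive.
#' @param constituents Named numeric vector of nonnegative concentrations.
#' @export
tissue_layer <- function(name, thickness_mm, constituents = numeric()) {
  stopifnot(is.numeric(thickness_mm), thickness_mm > 0)
  constituents <- unlist(constituents)
  if (length(constituents) && (is.null(names(constituents)) || any(constituents < 0)))
    stop("constituents must be a named vector of nonnegative concentrations",
         call. = FALSE)
  structure(list(name = name, thickness_mm = thickness_mm,
                 constituents = constituents), class = "tissue_layer")
}

#' Pigmented epidermis layer
#'
#' A 1 mm epidermis whose melanin content is split 78% eumelanin / 22%
#' pheomelanin. One melanin unit corresponds to light pigmentation and five
#' units to dark pigmentation.
#'
#' @param units Melanin units, positive (fractional allowed; the
#'   physiological range is 1--5).
#' @param melanosome Optional melanosome-scattering concentration (default 0,
#'   i.e. the scattering term is disabled).
#' @param thickness_mm Epidermis thickness, default 1 mm.
#' @export
melanin_layer <- function(units, melanosome = 0, thickness_mm = 1) {
  if (!is.numeric(units) || length(units) != 1 || units <= 0)
    stop("melanin units must be a single positive number", call. = FALSE)
  cons <- c(eumelanin = 0.78 * units, pheomelanin = 0.22 * units)
  if (melanosome > 0) cons <- c(cons, melanosome_scatter = melanosome)
  tissue_layer("epidermis", thickness_mm, cons)
}

#' Perfused dermis layer
#'
#' A 3 mm dermis whose hemoglobin is split between oxy- and deoxyhemoglobin
#' according to the arterial oxygen saturation.
#'
#' @param sao2 Oxygen saturation in percent, within `[0, 100]`.
#' @param total_hb Total hemoglobin concentration in model units.
#' @param thickness_mm Dermis thickness, default 3 mm.
#' @export
blood_layer <- function(sao2, total_hb = 1, thickness_mm = 3) {
  if (!is.numeric(sao2) || length(sao2) != 1 || sao2 < 0 || sao2 > 100)
    stop("sao2 must lie in [0, 100]", call. = FALSE)
  stopifnot(total_hb > 0)
  tissue_layer("dermis", thickness_mm,
               c(HbO2 = total_hb * sao2 / 100,
                 Hb = total_hb * (1 - sao2 / 100)))
}

#' Ordered tissue stack
#'
#' Layers ordered surface first. Per-layer attenuation fractions (the
#' proportion of light reaching each layer) are derived during propagation.
#'
#' @param ... [tissue_layer()] objects, surface first.
#' @export
tissue_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "tissue_layer")) layers <- layers[[1]]
  if (!all(vapply(layers, inherits, logical(1), "tissue_layer")))
    stop("all elements must be tissue_layer objects", call. = FALSE)
  structure(list(layers = layers, attenuation_fractions = NULL),
            class = "tissue_stack")
}

# Unshaded Beer-Lambert absorbance of one layer: sum_m [X]_m * eps_m(lambda) * l
layer_absorbance <- function(layer, spectra, grid) {
  g <- grid_values(grid)
  A <- numeric(length(g))
  cons <- layer$constituents
  for (nm in names(cons)) {
    sp <- spectra[[nm]]
    if (is.null(sp)) stop("no spectrum for chromophore '", nm, "'", call. = FALSE)
    if (length(sp$extinction) != length(g) || any(sp$wavelength != g))
      stop("spectrum grid mismatch for '", nm, "'", call. = FALSE)
    A <- A + cons[[nm]] * sp$extinction * layer$thickness_mm
  }
  A
}

#' Cumulative shaded absorbance of a tissue stack
#'
#' Sums per-layer Beer-Lambert absorbances weighted by the attenuation
#' fraction rho of each layer: the surface layer sees rho = 1 and each deeper
#' layer sees the fraction of light transmitted by everything above it
#' (`exp(-A_above)`), so rho is nonincreasing down the stack.
#'
#' @param stack A [tissue_stack()].
#' @param spectra Named list of [chromophore_spectrum()] covering every
#'   constituent.
#' @param grid A [wavelength_grid()].
#' @return Per-wavelength cumulative absorbance, with the per-layer rho
#'   values attached as attribute `"attenuation_fractions"` (a matrix,
#'   layers x wavelengths).
#' @export
cumulative_absorbance <- function(stack, spectra, grid = wavelength_grid()) {
  g <- grid_values(grid)
  n_layers <- length(stack$layers)
  A_total <- numeric(length(g))
  A_above <- numeric(length(g))
  rho <- matrix(1, nrow = max(n_layers, 1), ncol = length(g))
  for (i in seq_len(n_layers)) {
    rho_i <- exp(-A_above)
    rho[i, ] <- rho_i
    A_i <- layer_absorbance(stack$layers[[i]], spectra, grid)
    A_total <- A_total + rho_i * A_i
    A_above <- A_above + A_i
  }
  attr(A_total, "attenuation_fractions") <- rho
  A_total
}

#' Photon budget from cumulative absorbance
#'
#' Total light emission, in photon-count units, defined as 10 times the
#' maximum cumulative absorbance over the grid. A configurable floor guards
#' the degenerate all-transparent case.
#'
#' @param absorbance Per-wavelength cumulative absorbance (finite,
#'   nonnegative).
#' @param floor Budget returned when the absorbance is identically zero.
#' @export
photon_budget <- function(absorbance, floor = 1) {
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop("absorbance must be finite and nonnegative", call. = FALSE)
  m <- max(absorbance)
  if (m == 0) floor else 10 * m
}

#' Propagate LED light through a tissue stack
#'
#' Default subtractive model: the absorbance, convolved with the relative LED
#' emission, is subtracted from the total emission at each wavelength and
#' clamped at zero. The exponential mode applies Beer-Lambert transmission
#' `total * rel * exp(-A/total)`, which agrees with the subtractive model to
#' first order in the absorbance.
#'
#' @param emitter [make_led_spectrum()] with `total` set (see
#'   [photon_budget()]).
#' @param stack A [tissue_stack()].
#' @param spectra Named chromophore list.
#' @param detector A [detector_response()]; default flat.
#' @param grid A [wavelength_grid()] matching the emitter.
#' @param mode `"subtractive"` (default) or `"exponential"`.
#' @return `"transmission_result"`: per-wavelength `detected` intensity,
#'   `standardized` (divided by the LED maximum), `scalar_intensity`
#'   (detector-weighted sum), and a `clamped` flag marking wavelengths where
#'   the subtractive model hit zero.
#' @export
propagate <- function(emitter, stack, spectra, detector = NULL,
                      grid = wavelength_grid(),
                      mode = c("subtractive", "exponential")) {
  mode <- match.arg(mode)
  g <- grid_values(grid)
  if (length(emitter$relative) != length(g) || any(emitter$wavelength != g))
    stop("emitter grid mismatch", call. = FALSE)
  if (is.null(detector)) detector <- detector_response(grid)
  if (length(detector$relative) != length(g))
    stop("detector grid mismatch", call. = FALSE)
  total <- emitter$total
  if (!is.finite(total) || total <= 0)
    stop("emitter total not set; assign a photon budget first", call. = FALSE)
  A <- cumulative_absorbance(stack, spectra, grid)
  rho <- attr(A, "attenuation_fractions")
  A <- as.vector(A)
  rel <- emitter$relative
  if (mode == "subtractive") {
    raw <- total * rel - rel * A
    clamped <- raw < 0
    detected <- pmax(raw, 0)
  } else {
    detected <- total * rel * exp(-A / total)
    clamped <- rep(FALSE, length(g))
  }
  led_max <- total * max(rel)
  structure(list(wavelength = g,
                 detected = detected,
                 standardized = detected / led_max,
                 scalar_intensity = sum(detected * detector$relative),
                 clamped = clamped,
                 mode = mode,
                 absorbance = A,
                 attenuation_fractions = rho),
            class = "transmission_result")
}

#' Shared photon budget for a paired comparison
#'
#' The budget is fixed once from the darkest condition (default 5 melanin
#' units, 70% SaO2) over both LED bands, mirroring a device whose LED
#' brightness is kept identical across skin sites and oxygen levels.
#'
#' @param units_dark Melanin units of the reference (darkest) condition.
#' @param sao2 Reference saturation in percent.
#' @param total_hb Total hemoglobin, model units.
#' @param fwhm_nm LED full-width half-maximum.
#' @export
paired_photon_budget <- function(units_dark = 5, sao2 = 70, total_hb = 1,
                                 fwhm_nm = 30) {
  m <- 0
  for (ch in c("red", "nir")) {
    grid <- channel_band_grid(ch, fwhm_nm)
    spectra <- default_chromophores(grid)
    stack <- tissue_stack(melanin_layer(units_dark), blood_layer(sao2, total_hb))
    m <- max(m, max(cumulative_absorbance(stack, spectra, grid)))
  }
  10 * m
}

#' Staged transmission curves for one channel
#'
#' The three standardized curves: LED emission alone, LED plus the pigmented
#' epidermis, and LED plus epidermis and perfused dermis (default 80% SaO2).
#'
#' @param melanin_units Melanin units of the epidermis.
#' @param sao2 Dermis saturation in percent.
#' @param channel `"red"` (660 nm) or `"nir"` (940 nm).
#' @param total Photon budget; when `NULL`, computed from this condition's
#'   own full stack by the 10x rule.
#' @param total_hb Total hemoglobin, model units.
#' @param mode Propagation mode, see [propagate()].
#' @return List of three `"transmission_result"` objects named `led`,
#'   `epidermis`, `full`.
#' @export
simulate_transmission_curves <- function(melanin_units, sao2 = 80,
                                         channel = c("red", "nir"),
                                         total = NULL, total_hb = 1,
                                         mode = "subtractive") {
  channel <- match.arg(channel)
  grid <- channel_band_grid(channel)
  spectra <- default_chromophores(grid)
  emitter <- make_led_spectrum(channel_peak(channel), 30, grid)
  full_stack <- tissue_stack(melanin_layer(melanin_units),
                             blood_layer(sao2, total_hb))
  if (is.null(total))
    total <- photon_budget(cumulative_absorbance(full_stack, spectra, grid))
  emitter$total <- total
  det <- detector_response(grid)
  list(
    led = propagate(emitter, tissue_stack(list()), spectra, det, grid, mode),
    epidermis = propagate(emitter, tissue_stack(melanin_layer(melanin_units)),
                          spectra, det, grid, mode),
    full = propagate(emitter, full_stack, spectra, det, grid, mode)
  )
}

#' Effective channel gains of the pulsatile forward model
#'
#' Collapses the spectral model of one channel into three scalars so the
#' detected intensity for blood concentration `c` at saturation `s` (fraction)
#' is `S_base - c * (s * K_O + (1 - s) * K_D)`. `S_base` is the
#' detector-weighted intensity after the epidermis, and `K_O`/`K_D` are the
#' oxy-/deoxyhemoglobin absorption gains of the dermis, shaded by the
#' epidermis.
#'
#' @param melanin_units Epidermis melanin units.
#' @param channel `"red"` or `"nir"`.
#' @param total Photon budget (use [paired_photon_budget()] for paired
#'   comparisons).
#' @param fwhm_nm LED full-width half-maximum.
#' @param dermis_mm Dermis thickness in mm.
#' @export
channel_gains <- function(melanin_units, channel = c("red", "nir"), total,
                          fwhm_nm = 30, dermis_mm = 3) {
  channel <- match.arg(channel)
  grid <- channel_band_grid(channel, fwhm_nm)
  g <- grid_values(grid)
  spectra <- default_chromophores(grid)
  emitter <- make_led_spectrum(channel_peak(channel), fwhm_nm, grid)
  rel <- emitter$relative
  pd <- detector_response(grid)$relative
  epi <- melanin_layer(melanin_units)
  A_epi <- layer_absorbance(epi, spectra, grid)
  rho_derm <- exp(-A_epi)
  list(channel = channel, melanin_units = melanin_units, total = total,
       S_base = sum(pd * rel * pmax(total - A_epi, 0)),
       K_O = sum(pd * rel * rho_derm * spectra$HbO2$extinction * dermis_mm),
       K_D = sum(pd * rel * rho_derm * spectra$Hb$extinction * dermis_mm))
}

#' Model modulation ratio across saturation
#'
#' Analytic modulation ratio of the pulsatile forward model: the AC intensity
#' of each channel is the derivative of detected intensity with respect to
#' blood concentration (times a common pulsatile increment that cancels in
#' the ratio), and the DC intensity is the baseline detected intensity.
#'
#' @param sao2 Saturation values in percent (vectorized).
#' @param melanin_units Epidermis melanin units.
#' @param total Photon budget; default [paired_photon_budget()].
#' @param c0 Baseline blood concentration, model units.
#' @return Numeric vector of modulation ratios.
#' @export
r_model <- function(sao2, melanin_units, total = paired_photon_budget(), c0 = 1) {
  gr <- channel_gains(melanin_units, "red", total)
  gn <- channel_gains(melanin_units, "nir", total)
  s <- sao2 / 100
  ac_r <- s * gr$K_O + (1 - s) * gr$K_D
  ac_n <- s * gn$K_O + (1 - s) * gn$K_D
  dc_r <- gr$S_base - c0 * ac_r
  dc_n <- gn$S_base - c0 * ac_n
  (ac_r / dc_r) / (ac_n / dc_n)
}

#' Sensitivity of the model modulation ratio to saturation
#'
#' Least-squares slope of [r_model()] against SaO2 over a range, the
#' model-level analog of a per-trial calibration slope.
#'
#' @param melanin_units Epidermis melanin units.
#' @param sao2_range Endpoints in percent.
#' @param n_points Evaluation points across the range.
#' @param ... Passed to [r_model()].
#' @export
r_model_slope <- function(melanin_units, sao2_range = c(70, 100),
                          n_points = 31, ...) {
  s <- seq(sao2_range[1], sao2_range[2], length.out = n_points)
  r <- r_model(s, melanin_units, ...)
  unname(stats::coef(stats::lm(r ~ s))[2])
}
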