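#' Wavelength grid
#'
#' Uniformly spaced wavelength axis (nm) on which all spectra, LED emission
#' curves and tissue absorbances are evaluated.
#'
#' @param from,to Range in nm. Must lie within 300--1100 nm.
#' @param by Spacing in nm.
#' @return Numeric vector of wavelengths with class `"wavelength_grid"`.
#' @export
wavelength_grid <- function(from = 400, to = 1000, by = 1) {
  stopifnot(from < to, by > 0)
  if (from < 300 || to > 1100)
    stop("wavelength grid must lie within 300-1100 nm", call. = FALSE)
  g <- seq(from, to, by = by)
  class(g) <- c("wavelength_grid", "numeric")
  g
}

grid_values <- function(grid) as.numeric(grid)

#' Chromophore extinction spectrum
#'
#' Extinction (absorptivity) per model-unit concentration and mm path length,
#' tabulated on a wavelength grid. Concentrations are dimensionless "model
#' units"; one blood unit over the 3 mm dermis gives an optical depth of 0.9
#' at 660 nm for pure deoxyhemoglobin (the anchoring convention for all
#' shipped spectra).
#'
#' @param name One of `"eumelanin"`, `"pheomelanin"`, `"Hb"`, `"HbO2"`,
#'   `"melanosome_scatter"`, or any user label.
#' @param grid A [wavelength_grid()].
#' @param extinction Nonnegative extinction value per grid wavelength.
#' @return Object of class `"chromophore_spectrum"`.
#' @export
chromophore_spectrum <- function(name, grid, extinction) {
  g <- grid_values(grid)
  stopifnot(length(extinction) == length(g))
  if (any(!is.finite(extinction)) || any(extinction < 0))
    stop("extinction must be finite and nonnegative", call. = FALSE)
  structure(list(name = name, wavelength = g, extinction = as.numeric(extinction)),
            class = "chromophore_spectrum")
}

#' Read a chromophore table from CSV
#'
#' Expects columns `wavelength_nm` and `extinction`; values are linearly
#' interpolated onto `grid`.
#'
#' @param path CSV file path.
#' @param name Chromophore label.
#' @param grid Target [wavelength_grid()].
#' @param scale Multiplier applied after interpolation (unit conversion).
#' @export
read_chromophore_csv <- function(path, name, grid, scale = 1) {
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "extinction") %in% names(tab)))
    stop("chromophore CSV needs columns wavelength_nm, extinction", call. = FALSE)
  g <- grid_values(grid)
  if (min(g) < min(tab$wavelength_nm) || max(g) > max(tab$wavelength_nm))
    stop("grid extends beyond tabulated wavelengths", call. = FALSE)
  y <- stats::approx(tab$wavelength_nm, tab$extinction, xout = g)$y * scale
  chromophore_spectrum(name, grid, pmax(y, 0))
}

# Anchoring constants for the dimensionless concentration scale.
# Hb at 660 nm: 0.30 per unit per mm (so 1 blood unit x 3 mm dermis = 0.9).
# Melanin mix at 660 nm: 0.78*0.30 + 0.22*0.20 = 0.278 per melanin unit per mm
# in a 1 mm epidermis.
.HB660_TABLE <- 3226.56    # cm^-1/M value at 660 nm in the shipped table
.HB660_MODEL <- 0.30
.EU660 <- 0.30
.PH660 <- 0.20
.K_EUMELANIN <- 0.0062     # nm^-1 exponential decay constants
.K_PHEOMELANIN <- 0.0072

.chromophore_cache <- new.env(parent = emptyenv())

#' Default chromophore set
#'
#' Hemoglobin spectra come from the packaged synthetic reconstruction of the
#' public molar-extinction compilation (see
#' `inst/extdata/*_extinction_synthetic.csv`), rescaled to model units.
#' Eumelanin and pheomelanin are smooth exponentials in wavelength
#' (absorbance decaying with decay constants 0.0062 and 0.0072 per nm),
#' anchored at 660 nm. An optional melanosome scattering term is a power law
#' `~ lambda^-b`.
#'
#' @param grid A [wavelength_grid()].
#' @param hb_path,hbo2_path Optional CSV overrides for the hemoglobin tables.
#' @param melanosome_b Power-law exponent for the optional scattering term.
#' @param melanosome_scale Its value at 660 nm (0 disables; kept for
#'   completeness, the scattering term is off by default everywhere).
#' @return Named list of [chromophore_spectrum()] objects.
#' @export
default_chromophores <- function(grid = wavelength_grid(),
                                 hb_path = NULL, hbo2_path = NULL,
                                 melanosome_b = 3.48, melanosome_scale = 0) {
  g <- grid_values(grid)
  key <- paste(g[1], g[length(g)], length(g), hb_path %||% "", hbo2_path %||% "",
               melanosome_b, melanosome_scale, sep = "|")
  cached <- get0(key, envir = .chromophore_cache)
  if (!is.null(cached)) return(cached)
  if (is.null(hb_path))
    hb_path <- system.file("extdata", "hb_extinction_synthetic.csv", package = "ppgbias")
  if (is.null(hbo2_path))
    hbo2_path <- system.file("extdata", "hbo2_extinction_synthetic.csv", package = "ppgbias")
  s <- .HB660_MODEL / .HB660_TABLE
  out <- list(
    Hb    = read_chromophore_csv(hb_path, "Hb", grid, scale = s),
    HbO2  = read_chromophore_csv(hbo2_path, "HbO2", grid, scale = s),
    eumelanin = chromophore_spectrum("eumelanin", grid,
                                     .EU660 * exp(-.K_EUMELANIN * (g - 660))),
    pheomelanin = chromophore_spectrum("pheomelanin", grid,
                                       .PH660 * exp(-.K_PHEOMELANIN * (g - 660)))
  )
  if (melanosome_scale > 0)
    out$melanosome_scatter <- chromophore_spectrum(
      "melanosome_scatter", grid, melanosome_scale * (660 / g)^melanosome_b)
  assign(key, out, envir = .chromophore_cache)
  out
}

#' Gaussian LED emission spectrum
#'
#' Peak-normalized Gaussian with the stated full-width half-maximum; the
#' total photon budget is set separately (see [photon_budget()]).
#'
#' @param peak_nm Center wavelength, must lie on the grid range.
#' @param fwhm_nm Full-width half-maximum in nm.
#' @param grid A [wavelength_grid()].
#' @return Object of class `"emitter_spectrum"` with fields `relative`
#'   (unit peak) and `total` (photon budget, `NA` until set).
#' @export
make_led_spectrum <- function(peak_nm, fwhm_nm, grid = wavelength_grid()) {
  g <- grid_values(grid)
  if (peak_nm < min(g) || peak_nm > max(g))
    stop("LED peak outside wavelength grid", call. = FALSE)
  stopifnot(fwhm_nm > 0)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  rel <- exp(-(g - peak_nm)^2 / (2 * sigma^2))
  structure(list(peak_nm = peak_nm, fwhm_nm = fwhm_nm, sigma_nm = sigma,
                 wavelength = g, relative = rel, total = NA_real_),
            class = "emitter_spectrum")
}

#' Photodiode spectral response
#'
#' Relative current response per wavelength, values in `[0, 1]`. The default
#' is flat response.
#'
#' @param grid A [wavelength_grid()].
#' @param relative Scalar or per-wavelength response.
#' @export
detector_response <- function(grid = wavelength_grid(), relative = 1) {
  g <- grid_values(grid)
  rel <- rep_len(relative, length(g))
  if (any(rel < 0) || any(rel > 1))
    stop("detector response must lie in [0, 1]", call. = FALSE)
  structure(list(wavelength = g, relative = rel), class = "detector_response")
}

#' Band-limited wavelength grid for one LED channel
#'
#' Peak +/- 2 FWHM at 1 nm spacing, the integration bounds for that
#' channel's spectral emission (red: 600--720 nm, NIR: 880--1000 nm at the
#' default FWHM).
#'
#' @param channel `"red"` (660 nm peak) or `"nir"` (940 nm peak).
#' @param fwhm_nm LED full-width half-maximum in nm.
#' @export
channel_band_grid <- function(channel = c("red", "nir"), fwhm_nm = 30) {
  channel <- match.arg(channel)
  peak <- if (channel == "red") 660 else 940
  wavelength_grid(peak - 2 * fwhm_nm, peak + 2 * fwhm_nm, by = 1)
}

#' Peak emission wavelength of a channel
#' @param channel `"red"` or `"nir"`.
#' @export
channel_peak <- function(channel) if (channel == "red") 660 else 940
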