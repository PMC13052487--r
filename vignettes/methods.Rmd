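---
title: "How ppgbias models pigmentation bias in pulse oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ppgbias models pigmentation bias in pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pulse oximeters estimate arterial oxygen saturation (SpO2) from the ratio of
pulsatile light absorption at two wavelengths, red (660 nm) and near-infrared
(940 nm). Melanin in the epidermis absorbs strongly in the red and weakly in
the NIR, so pigmented skin removes red photons before they ever reach the
pulsating dermal vasculature. The clinical consequence is well documented:
oximeters overestimate saturation in patients with dark skin, most severely
in hypoxemia (occult hypoxemia). `ppgbias` implements the complete
computational chain needed to study this mechanism on synthetic data: a
spectral forward model of layered tissue, a generator of paired
pigmented/nonpigmented deoxygenation-trial PPG recordings, a DSP and
signal-quality pipeline, and the pigmentation-stratified regression
statistics.

## The forward model

Light from an LED with a Gaussian emission spectrum (peak 660 or 940 nm,
FWHM 30 nm) traverses an epidermis (1 mm) containing melanin — 78% eumelanin
and 22% pheomelanin, on a dimensionless 1 (light) to 5 (dark) unit scale —
and a dermis (3 mm) containing hemoglobin whose oxy/deoxy split is set by
SaO2. Each layer contributes a Beer–Lambert absorbance
$[X]\,\varepsilon_\lambda\, l$; a layer below the surface only receives the
fraction $\rho_\lambda = e^{-A_{\mathrm{above}}(\lambda)}$ transmitted by the
layers above it, so the cumulative absorbance is the $\rho$-weighted sum over
layers. The total photon budget is ten times the maximum cumulative
absorbance, and the detected spectrum is the budget-scaled LED emission minus
the absorbance convolved with the emission curve, clamped at zero
(`propagate()`, subtractive mode). An exponential Beer–Lambert mode
(`total * rel * exp(-A/total)`) is available as a configuration option and
agrees with the subtractive mode to first order in the absorbance.

Numerical choices worth stating explicitly:

* **Integration bounds.** Each channel is integrated over its own LED band
  (peak ± 2 FWHM) — the natural bounds of the emission integral. Integrating
  over the full 400–1000 nm grid instead would let the hemoglobin Soret peak
  near 430 nm, which neither LED illuminates, dominate the photon budget.
* **One budget per comparison.** The photon budget is computed once, at the
  darkest condition (5 units, 70% SaO2) over both channel bands, and reused
  for every condition being compared (`paired_photon_budget()`). This mirrors
  a device whose LED brightness is fixed across sites, and it is what makes
  detected intensity monotone in melanin; recomputing the 10x rule per
  condition would brighten the LED whenever absorbance rises.
* **Spectra.** The hemoglobin tables shipped in `inst/extdata` are smooth
  monotone reconstructions through landmark values of the public
  molar-extinction compilations (Soret peaks, the HbO2 540/576 doublet, the
  Hb 555 peak, the 660/940 values, the ~800 nm isosbestic point); they are
  labelled synthetic and only their orderings and smooth shape carry weight.
  Eumelanin and pheomelanin are exponentials in wavelength (decay constants
  0.0062 and 0.0072 per nm), the standard description of melanin absorbance.
  Concentrations are dimensionless model units anchored so that one blood
  unit across the 3 mm dermis has optical depth 0.9 at 660 nm for pure Hb;
  only ratios and orderings are ever asserted.
* **Melanosome scattering** is representable as an optional power-law
  term (`default_chromophores(melanosome_scale=)`) but is disabled by
  default: no quantitative spectrum is available for it.
* **Clamping.** The subtractive model can drive detected intensity negative
  at strongly absorbed wavelengths; it is clamped at zero and flagged
  (`$clamped`).

The analytic modulation ratio `r_model(sao2, units)` collapses each channel
to three gains (baseline intensity after the epidermis, and the shaded
oxy/deoxy absorption gains of the dermis). Its slope against SaO2 over
70–100% is the model-level statement of the headline effect: at 5 melanin
units the slope magnitude is roughly 40% of its 1-unit value, because the
epidermis multiplies the red pulsatile component by
$e^{-A_{\mathrm{epi}}(660)}$ while barely touching the NIR.

## The synthetic trials

`make_paired_trial()` emulates one deoxygenation trial: a normalized
logistic SaO2 ramp from 100% to 70% (desk-scale default 600 s; the animal
trials this emulates ran ~40 min), ~10 arterial-blood-gas samples at
stratified-uniform times, and two simultaneous recordings that share the
profile and differ only in melanin units and noise realization. Each record
evaluates the forward model at 120 Hz and block-averages every three samples
to 40 Hz. The dermal blood concentration is

$$c(t) = c_0\,(1 + \beta\,\sin 2\pi f_r t) + \Delta c\; g(t)\, p(t),$$

with a raised-cosine/exponential-decay beat shape $p$ at 1.8 Hz (period
jittered ±3%), respiration at 0.4 Hz ($\beta = 0.05$), and a slow AR(1)
amplitude drift $g$ (sd 0.08, 30 s time constant) standing in for
vasomotion. Defaults were chosen once as physiologically plausible mid-band
values:

* **Pulse amplitude** $\Delta c = 0.3\,c_0$, multiplied per record by a
  lognormal site-perfusion factor (sd of log 0.6). The factor is shared by
  both wavelengths of a record — the same blood pulses under both LEDs — so
  it cancels exactly in the modulation ratio but gives the realistic
  between-site spread in pulsatility indices that makes per-trial PI slopes
  genuinely variable.
* **Noise.** White sensor noise (0.2x) and a 6–14 Hz band-limited component
  (0.1x), both relative to the channel's analytic cardiac AC RMS, so the
  signal-to-noise ratio is comparable across pigmentation; with these levels
  essentially all windows pass the printed quality thresholds, while scaling
  the amplitudes 20-fold fails most of them.
* **Sensor gain drift**, multiplicative per channel (sd 0.1%, spline knots
  every 60 s), models LED/coupling drift. Because it scales AC and DC of a
  channel together it cancels in the modulation ratio and PI but perturbs
  the AC and DC ratios individually. It is deliberately band-limited: any
  appreciable within-window ramp leaks across the spectrum and corrupts the
  spectral-moment quality indices, which the emulated hardware avoided by
  high-pass filtering before sampling — something a faithful digital
  reimplementation cannot do.
* **Motion artifacts** (smooth low-frequency transients) are available but
  off by default; they exist to exercise the quality-gating logic.

What the generator does *not* emulate: dicrotic-notch morphology, venous
pulsation, probe-contact mechanics, and any pigmentation-correlated
difference in noise floor. Passing tests therefore demonstrate that the
pipeline recovers the optical mechanism under controlled conditions, not
that it would survive every artifact of animal data.

## The DSP and signal-quality pipeline

Each record is filtered once — median filter (10 samples), clipping of
samples deviating more than 10% from the global mean with linear
interpolation, an exponentially weighted moving average (alpha 0.2), and a
zero-phase fourth-order Chebyshev-II low-pass (stopband 10 Hz, 40 dB) — and
then cut into 10 s windows hopped by 5 s, a short-time Fourier analysis.
Per window and channel, hard FFT masks (half-open bands, conjugate-symmetric
zeroing, no taper) extract the pulsatile component (0.75–4 Hz, then a
periodic moving average over 3 periods at the autocorrelation-estimated
beat lag, summarized by RMS), the baseline (<0.5 Hz plus a 5 s moving
average, summarized by the mean) and the high-frequency component (>6 Hz,
RMS). Window length and hop are package choices (the procedure's source
never states them): 10 s holds at least seven beats at the 0.75 Hz band
edge, and 5 s hops give ~119 windows per 600 s trial against ~10 ABGs.
Filter edges use shrinking windows, and the Chebyshev stage uses
odd-reflection padding, so no data are fabricated at the boundaries.

Five quality indices gate every window: pulsatility index ((max-min)/mean),
relative cardiac-band power from a Welch PSD (4 s Hann segments, 50%
overlap), spectral skewness and kurtosis of the magnitude spectrum above
0.3 Hz (the sub-0.3 Hz bins would otherwise dominate the moments), and the
maximum autocorrelation over cardiac lags (fs/4 to fs/0.75 samples). The
printed exclusion floors are 5e-5, 5e-9, 4, 30 and 0.4; a window failing any
one metric on either channel is removed. Two printed conventions are
reproduced deliberately even though they look odd: the (N-1)-denominator
moment formulas, and the rPSD floor of 5e-9 — a ratio bounded by 1 can never
fall below it, so that gate is effectively inert (it remains configurable).
Time-domain skewness and kurtosis are computed and reported but not
thresholded, following the printed threshold list exactly.

## The statistics

Per trial and arm, the ABG-matched windows (nearest valid window center
within 10 s; unmatched ABGs dropped and counted) feed ordinary least squares
of each metric — modulation ratio R = RAC x RDC, the AC ratio (red/NIR), the
DC ratio (NIR/red), and per-channel PI — against SaO2. The AC magnitude
defaults to the RMS estimator, with max-min available by configuration;
both are legitimate printed definitions and agree within ~10% on clean
windows. All trial-level inference uses the df = n - 3 convention (two line
parameters plus the animal), applied consistently: residual variance,
standard errors and p-values. Two tests carry the conclusions:

* `paired_slope_test()` — one-sample t on within-pair (nonpigmented minus
  pigmented) differences of per-trial slopes or intercepts, df = n_pairs - 3.
* `difference_regression_test()` — pool the per-timepoint metric differences
  across trials, regress on SaO2, and t-test the slope (df = n - 3). The
  within-trial correlation of pooled points is ignored, reproducing the
  published procedure as printed.

On 20 default trials the pipeline reproduces the full published structure:
pigmented |slope| of R vs SaO2 below nonpigmented in every trial with the
paired test rejecting decisively; the red PI sensitivity attenuated (pooled
difference regression significant) while the NIR PI difference is not; and
the DC-ratio effect carried by its intercept. One caveat is documented
rather than engineered away: in near-noiseless synthetic data the tiny
residual DC-ratio *slope* difference (about 1% of the AC-ratio effect) can
still reach formal significance, so the package's property tests assert the
structural form — intercept-dominated DC effect, slope bias driven by the
AC ratio — not the underpowered non-rejection.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale sizes chosen as
package defaults: 600 s trials (20 for the recovery analysis), 10 ABGs per
trial, and 200–400 reduced-size replicates (10 pairs x 60 s, 6 ABGs) for the
type-I check of the paired test, whose rejection rate sits slightly below
5% — the df = n - 3 convention compares a statistic with n - 1 effective
degrees of freedom against heavier-tailed quantiles and is therefore mildly
conservative. Every stochastic component descends from a single integer
seed; identical seeds give byte-identical datasets and experiment summaries.

## Known limitations

* The subtractive propagation mixes photon counts with absorbance, as
  specified by the procedure it implements; the clamp at zero is flagged but
  physically ad hoc. The exponential mode is the physically consistent
  alternative.
* Concentrations, intensities and therefore the quality thresholds are in
  arbitrary device-like units; only orderings, ratios and threshold
  crossings are meaningful.
* `estimate_period()` needs a positive autocorrelation peak of at least 0.2;
  windows without one skip the periodic moving average and are typically
  rejected by the quality gates anyway.
* Trial storage is CSV-based (`write_trial()`/`read_trial()`); records
  round-trip exactly through full-precision text.
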