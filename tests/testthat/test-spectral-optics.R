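test_that("LED emission is a peak-normalized Gaussian with the stated FWHM", {
  grid <- wavelength_grid()
  led <- make_led_spectrum(660, 30, grid)
  g <- as.numeric(grid)
  expect_equal(led$relative[g == 660], 1)
  expect_equal(led$relative[g == 645], 0.5, tolerance = 1e-12)
  expect_equal(led$relative[g == 675], 0.5, tolerance = 1e-12)
  # one FWHM from the peak a Gaussian sits at exactly 1/16 of its maximum
  expect_equal(led$relative[g == 630], 1 / 16, tolerance = 1e-12)
  expect_equal(led$relative[g == 690], 1 / 16, tolerance = 1e-12)

  nir <- make_led_spectrum(940, 30, grid)
  for (d in c(5, 17, 40))
    expect_equal(nir$relative[g == 940 - d], nir$relative[g == 940 + d])

  expect_error(make_led_spectrum(1050, 30, grid), "outside")
})

test_that("cumulative absorbance is the rho-weighted Beer-Lambert sum", {
  grid <- toy_grid()
  spectra <- list(a = toy_spectrum("a", c(2, 1, 0.5)),
                  b = toy_spectrum("b", c(0.3, 0.4, 0.5)))

  empty <- tissue_stack(tissue_layer("epidermis", 1, c(a = 0, b = 0)))
  expect_equal(as.numeric(cumulative_absorbance(empty, spectra, grid)),
               c(0, 0, 0))

  one <- tissue_stack(tissue_layer("epidermis", 1, c(a = 1)))
  expect_equal(as.numeric(cumulative_absorbance(one, spectra, grid)),
               c(2, 1, 0.5))

  # two chromophores over two layers, against a hand-summed oracle:
  # layer 1 unshaded, layer 2 shaded by exp(-A1)
  st <- tissue_stack(tissue_layer("epidermis", 2, c(a = 0.5)),
                     tissue_layer("dermis", 3, c(a = 0.25, b = 2)))
  A1 <- 0.5 * c(2, 1, 0.5) * 2
  A2 <- (0.25 * c(2, 1, 0.5) + 2 * c(0.3, 0.4, 0.5)) * 3
  expect_equal(as.numeric(cumulative_absorbance(st, spectra, grid)),
               A1 + exp(-A1) * A2, tolerance = 1e-12)
  rho <- attr(cumulative_absorbance(st, spectra, grid), "attenuation_fractions")
  expect_equal(rho[1, ], rep(1, 3))
  expect_true(all(rho[2, ] <= rho[1, ]))

  expect_error(cumulative_absorbance(
    tissue_stack(tissue_layer("epidermis", 1, c(zz = 1))), spectra, grid),
    "no spectrum")
})

test_that("photon budget follows the 10x-maximum rule with a floor", {
  A <- c(0.2, 3.7, 1.1)
  expect_equal(photon_budget(A), 37)
  expect_equal(photon_budget(c(0, 0, 0)), 1)
  expect_equal(photon_budget(c(0, 0, 0), floor = 5), 5)
  for (m in c(0.01, 1, 250)) expect_equal(photon_budget(c(m / 2, m)) / m, 10)
  expect_error(photon_budget(c(-1, 2)), "nonnegative")
})

test_that("propagation through a transparent medium returns the LED spectrum", {
  grid <- channel_band_grid("red")
  spectra <- default_chromophores(grid)
  led <- make_led_spectrum(660, 30, grid)
  led$total <- 12
  res <- propagate(led, tissue_stack(list()), spectra, grid = grid)
  expect_equal(res$detected, 12 * led$relative)
  expect_equal(max(res$standardized), 1)
  expect_false(any(res$clamped))
})

test_that("detected intensity decreases with melanin, red faster than NIR", {
  total <- paired_photon_budget()
  scalar <- function(units, ch) {
    grid <- channel_band_grid(ch)
    spectra <- default_chromophores(grid)
    led <- make_led_spectrum(channel_peak(ch), 30, grid)
    led$total <- total
    propagate(led, tissue_stack(melanin_layer(units), blood_layer(80)),
              spectra, grid = grid)$scalar_intensity
  }
  red <- vapply(1:5, scalar, numeric(1), ch = "red")
  nir <- vapply(1:5, scalar, numeric(1), ch = "nir")
  expect_true(all(diff(red) < 0))
  expect_true(all(diff(nir) < 0))
  frac_red <- -diff(red) / red[-5]
  frac_nir <- -diff(nir) / nir[-5]
  expect_true(all(frac_red > frac_nir))
})

test_that("melanin and blood layers encode the stated composition", {
  m1 <- melanin_layer(1)
  expect_equal(unname(m1$constituents["eumelanin"]), 0.78)
  expect_equal(unname(m1$constituents["pheomelanin"]), 0.22)
  expect_equal(m1$thickness_mm, 1)
  m5 <- melanin_layer(5)
  expect_equal(m5$constituents, 5 * m1$constituents)
  expect_error(melanin_layer(0), "positive")
  expect_error(melanin_layer(-2), "positive")

  b <- blood_layer(100, total_hb = 2)
  expect_equal(unname(b$constituents["Hb"]), 0)
  expect_equal(unname(b$constituents["HbO2"]), 2)
  expect_equal(b$thickness_mm, 3)
  b70 <- blood_layer(70)
  expect_equal(unname(b70$constituents["HbO2"] / b70$constituents["Hb"]), 7 / 3)
  expect_equal(unname(blood_layer(0)$constituents["HbO2"]), 0)
  expect_error(blood_layer(101), "\\[0, 100\\]")
})

test_that("staged transmission curves order and separate by pigmentation", {
  s1 <- simulate_transmission_curves(1, channel = "red")
  expect_true(all(s1$led$standardized >= s1$epidermis$standardized - 1e-12))
  expect_true(all(s1$epidermis$standardized >= s1$full$standardized - 1e-12))

  # shared budget so the two pigmentation conditions are comparable
  total <- paired_photon_budget()
  s1 <- simulate_transmission_curves(1, channel = "red", total = total)
  s5 <- simulate_transmission_curves(5, channel = "red", total = total)
  g <- s1$led$wavelength
  expect_lt(s5$epidermis$standardized[g == 660], s1$epidermis$standardized[g == 660])

  n1 <- simulate_transmission_curves(1, channel = "nir", total = total)
  n5 <- simulate_transmission_curves(5, channel = "nir", total = total)
  loss <- function(a, b) 1 - b$epidermis$scalar_intensity / a$epidermis$scalar_intensity
  expect_gt(loss(s1, s5), loss(n1, n5))
})

test_that("default chromophore spectra satisfy the physiological orderings", {
  grid <- wavelength_grid()
  sp <- default_chromophores(grid)
  g <- as.numeric(grid)
  expect_gt(sp$Hb$extinction[g == 660], sp$HbO2$extinction[g == 660])
  expect_gt(sp$HbO2$extinction[g == 940], sp$Hb$extinction[g == 940])
  expect_true(all(diff(sp$eumelanin$extinction) < 0))
  expect_true(all(diff(sp$pheomelanin$extinction) < 0))
  expect_true(all(sp$Hb$extinction >= 0) && all(sp$HbO2$extinction >= 0))
})

test_that("scalar intensity is stable under grid refinement", {
  total <- paired_photon_budget()
  scalar <- function(by) {
    grid <- wavelength_grid(600, 720, by)
    spectra <- default_chromophores(grid)
    led <- make_led_spectrum(660, 30, grid)
    led$total <- total
    # normalize by bin width so the quadrature is comparable across spacings
    propagate(led, tissue_stack(melanin_layer(3), blood_layer(80)),
              spectra, grid = grid)$scalar_intensity * by
  }
  expect_lt(abs(scalar(0.5) - scalar(1)) / scalar(1), 0.005)
})

test_that("exponential and subtractive propagation agree to first order", {
  grid <- channel_band_grid("red")
  spectra <- default_chromophores(grid)
  led <- make_led_spectrum(660, 30, grid)
  led$total <- 1000   # budget >> absorbance, the small-absorbance regime
  st <- tissue_stack(melanin_layer(1), blood_layer(80))
  sub <- propagate(led, st, spectra, grid = grid, mode = "subtractive")
  ex <- propagate(led, st, spectra, grid = grid, mode = "exponential")
  keep <- led$relative > 0.05
  expect_lt(max(abs(ex$detected[keep] - sub$detected[keep]) /
                  sub$detected[keep]), 1e-5)
})
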