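make_decomp <- function(red, nir, fs = 40) {
  w <- analysis_window(0, length(red) / fs, red, nir, fs)
  decompose_window(w)
}

test_that("modulation-ratio algebra holds for window metrics", {
  t <- (0:399) / 40
  x <- 1 + 0.02 * sin(2 * pi * 1.5 * t)
  m_eq <- window_metrics(make_decomp(x, x))
  expect_equal(m_eq$r, 1, tolerance = 1e-10)
  expect_equal(m_eq$rac, 1, tolerance = 1e-10)
  expect_equal(m_eq$rdc, 1, tolerance = 1e-10)

  m1 <- window_metrics(make_decomp(x, 1 + 0.05 * sin(2 * pi * 1.5 * t)))
  m2 <- window_metrics(make_decomp(2 * x, 1 + 0.05 * sin(2 * pi * 1.5 * t)))
  expect_equal(m2$rac, 2 * m1$rac, tolerance = 1e-8)
  expect_equal(m2$rdc, m1$rdc / 2, tolerance = 1e-8)
  expect_equal(m2$r, m1$r, tolerance = 1e-8)
  expect_equal(m1$r, m1$rac * m1$rdc, tolerance = 1e-12)
})

test_that("window metrics recover planted amplitude ratios", {
  t <- (0:399) / 40
  a_r <- 0.004; m_r <- 1.2; a_n <- 0.01; m_n <- 2.1
  red <- m_r + a_r * sin(2 * pi * 1.5 * t)
  nir <- m_n + a_n * sin(2 * pi * 1.5 * t)
  m <- window_metrics(make_decomp(red, nir))
  truth <- (a_r / m_r) / (a_n / m_n)
  expect_lt(abs(m$r - truth) / truth, 0.05)
  expect_lt(abs(m$pi_red - a_r / m_r / sqrt(2)) / (a_r / m_r / sqrt(2)), 0.05)
})

test_that("time- and frequency-domain metrics agree on clean windows", {
  t <- (0:399) / 40
  red <- 1.2 + 0.004 * sin(2 * pi * 1.5 * t)
  nir <- 2.1 + 0.010 * sin(2 * pi * 1.5 * t)
  d <- make_decomp(red, nir)
  mt <- window_metrics(d, domain = "time")
  mf <- window_metrics(d, domain = "frequency")
  for (col in c("r", "rac", "rdc", "pi_red", "pi_nir"))
    expect_lt(abs(mf[[col]] - mt[[col]]) / abs(mt[[col]]), 0.10)
})

test_that("trial regression equals the normal-equation solution", {
  pts <- data.frame(s = c(72, 80, 88, 96), y = -0.02 * c(72, 80, 88, 96) + 3)
  f <- fit_trial_regression(pts$s, pts$y)
  expect_equal(f$slope, -0.02, tolerance = 1e-12)
  expect_equal(f$intercept, 3, tolerance = 1e-12)
  expect_equal(f$r2, 1)

  two <- fit_trial_regression(c(70, 100), c(1, 0.4))
  expect_equal(two$r2, 1)
  expect_equal(unname(coef(two)["slope"]), -0.02, tolerance = 1e-12)

  set.seed(16)
  for (i in 1:10) {
    s <- runif(12, 70, 100)
    y <- rnorm(12)
    f <- fit_trial_regression(s, y)
    beta <- bf_ols(s, y)
    expect_rel_equal(c(f$intercept, f$slope), beta, 1e-10)
    expect_equal(f$df, 9)
  }
  expect_error(fit_trial_regression(rep(80, 5), rnorm(5)), "degenerate")
})

test_that("paired test follows the hand t-formula with df = n - 3", {
  f <- function(sl) list(slope = sl, intercept = 0)
  same <- lapply(c(-1, -2, -3, -4), f)
  p0 <- paired_slope_test(same, same)
  expect_equal(p0$t, 0)
  expect_equal(p0$p, 1)

  shift <- lapply(c(-2, -3, -4, -5, -6, -7), f)
  base <- lapply(c(-1, -2, -3, -4, -5, -6), f)
  pz <- paired_slope_test(shift, base)          # constant differences
  expect_true(is.infinite(pz$t))
  expect_equal(pz$p, 0)
  expect_true(pz$underflow)

  set.seed(17)
  a <- rnorm(8); b <- rnorm(8)
  pt_ <- paired_slope_test(lapply(b, f), lapply(a, f))
  d <- a - b
  expect_equal(pt_$t, mean(d) / (sd(d) / sqrt(8)), tolerance = 1e-12)
  expect_equal(pt_$df, 5)
  expect_equal(pt_$p, 2 * pt(-abs(pt_$t), 5), tolerance = 1e-12)
})

test_that("difference regression detects a planted pigmentation gap", {
  set.seed(18)
  s <- runif(60, 70, 100)
  zero <- data.frame(sao2 = s, nonpigmented = 1, pigmented = 1)
  f0 <- difference_regression_test(zero)
  expect_equal(f0$slope, 0)

  gap <- data.frame(sao2 = s,
                    nonpigmented = 0.01 * (100 - s) + rnorm(60, 0, 0.01),
                    pigmented = 0)
  f1 <- difference_regression_test(gap)
  expect_equal(f1$slope, -0.01, tolerance = 0.25)
  expect_lt(f1$p_slope, 0.05)

  one <- data.frame(sao2 = s[1:10], nonpigmented = rnorm(10), pigmented = 0)
  expect_equal(difference_regression_test(one)$slope,
               fit_trial_regression(one$sao2, one$nonpigmented)$slope)
})

test_that("ABG matching picks nearest valid windows and drops orphans", {
  metrics <- data.frame(time_s = seq(5, 595, by = 5), r = 1)
  metrics$valid <- TRUE
  metrics$valid[metrics$time_s > 200 & metrics$time_s < 300] <- FALSE
  abg <- data.frame(time_s = c(50, 250, 400), sao2 = c(95, 85, 75))
  m <- metrics_at_abg(metrics, abg, max_gap_s = 10)
  expect_equal(nrow(m), 2)                      # the 250 s ABG has no window
  expect_equal(attr(m, "n_dropped"), 1)
  expect_equal(m$time_s[1], 50)                 # exact center match

  ten <- data.frame(time_s = seq(30, 570, length.out = 10), sao2 = 100:91)
  m10 <- metrics_at_abg(metrics[metrics$time_s < 200 | metrics$time_s > 300, ],
                        ten)
  expect_lte(attr(m10, "n_dropped"), 2)
})

test_that("agreement R2 is 1 for identical series and low under independence", {
  x <- sin(1:100)
  a <- agreement_r2(x, x)
  expect_equal(a$r2_all, 1)
  expect_equal(a$r2_adjusted, 1)

  set.seed(19)
  low <- vapply(1:100, function(i)
    agreement_r2(rnorm(100), rnorm(100))$r2_all < 0.1, logical(1))
  expect_gte(mean(low), 0.9)

  # masking corrupted windows can only help on planted data, in expectation
  set.seed(20)
  gains <- replicate(100, {
    truth <- sin(seq(0, 6, length.out = 80))
    a1 <- truth + rnorm(80, 0, 0.05)
    a2 <- truth + rnorm(80, 0, 0.05)
    bad <- sample(80, 15)
    a1[bad] <- a1[bad] + rnorm(15, 0, 2)       # corrupted windows
    valid <- !(seq_len(80) %in% bad)
    g <- agreement_r2(a1, a2, valid)
    g$r2_adjusted - g$r2_all
  })
  expect_gt(mean(gains), 0)
})
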