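fs <- 500
t_axis <- seq_len(1500) / fs

test_that("band power isolates the oscillation's own band", {
  x <- sin(2 * pi * 10 * t_axis)                 # unit amplitude, 10 Hz
  expect_equal(band_power(x, band_def(8, 12), fs)[[1]], 0.5,
               tolerance = 0.05)                 # A^2 / 2
  expect_lt(band_power(x, band_def(20, 24), fs)[[1]], 0.005)

  # white noise: flat spectrum, power proportional to bandwidth
  ratios <- vapply(1:20, function(s) {
    z <- withr::with_seed(s, rnorm(6000))
    band_power(z, band_def(8, 12), fs)[[1]] /
      band_power(z, band_def(8, 16), fs)[[1]]
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.06)

  expect_error(band_power(x, band_def(200, 260), fs), "Nyquist")
})

test_that("band powers are near-additive over disjoint bands", {
  # per-realization fluctuation is a few percent; the systematic mismatch
  # (corner double-counting vs effective-bandwidth excess) must stay small
  rel <- vapply(1:20, function(s) {
    z <- withr::with_seed(s, rnorm(6000))
    lo <- band_power(z, band_def(8, 12), fs)[[1]]
    hi <- band_power(z, band_def(12, 16), fs)[[1]]
    both <- band_power(z, band_def(8, 16), fs)[[1]]
    (lo + hi - both) / both
  }, numeric(1))
  expect_lt(abs(mean(rel)), 0.05)
  expect_true(all(band_power(withr::with_seed(3, matrix(rnorm(3000), 2)),
                             band_def(8, 12), fs) >= 0))
})

test_that("periodogram band power integrates the spectrum correctly", {
  # sinusoid: all power in its own band
  x <- sin(2 * pi * 10 * t_axis)
  expect_equal(band_power(x, band_def(8, 12), fs,
                          method = "periodogram")[[1]], 0.5,
               tolerance = 1e-6)
  # white noise: flat density, band power = bandwidth / (fs / 2)
  v <- vapply(1:20, function(s)
    band_power(withr::with_seed(400 + s, rnorm(3000)), band_def(8, 12),
               fs, method = "periodogram")[[1]], numeric(1))
  expect_equal(mean(v), 4 / 250, tolerance = 0.1)
})

test_that("AR coefficients recover generating processes", {
  # AR(1), coefficient 0.8
  co1 <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, as.numeric(arima.sim(list(ar = 0.8), 1500)))
    ar_coefficients(x, 1)[1]
  }, numeric(1))
  expect_equal(mean(co1), 0.8, tolerance = 0.02)

  # white noise has no serial structure
  co0 <- vapply(1:20, function(s)
    ar_coefficients(withr::with_seed(100 + s, rnorm(1500)), 1)[1],
    numeric(1))
  expect_lt(abs(mean(co0)), 0.02)

  # AR(2) recovery: mean absolute error under 0.05
  phi <- c(0.5, -0.3)
  err <- vapply(1:20, function(s) {
    x <- withr::with_seed(200 + s, as.numeric(arima.sim(list(ar = phi),
                                                        1500)))
    mean(abs(ar_coefficients(x, 2) - phi))
  }, numeric(1))
  expect_lt(mean(err), 0.05)

  # agreement with the OLS autoregression in stats
  x <- withr::with_seed(9, as.numeric(arima.sim(list(ar = phi), 1500)))
  ref <- as.numeric(stats::ar.ols(x, aic = FALSE, order.max = 2,
                                  demean = TRUE, intercept = FALSE)$ar)
  expect_equal(ar_coefficients(x, 2), ref, tolerance = 1e-6,
               ignore_attr = TRUE)

  # degenerate design is flagged, not an error
  flat <- ar_coefficients(rep(2, 200), 3)
  expect_true(attr(flat, "degenerate"))
})

test_that("AR feature vectors concatenate to n_channels * order", {
  ep <- withr::with_seed(4, matrix(rnorm(30 * 300), nrow = 30))
  expect_length(ar_features(ep, 4), 120)
})

make_var_epochs <- function(n, nc, boost_ch = NULL, boost = 1, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    e <- matrix(rnorm(nc * 500), nrow = nc)
    if (!is.null(boost_ch)) e[boost_ch, ] <- boost * e[boost_ch, ]
    e
  }))
}

test_that("CSP finds the channel that separates the classes", {
  # class B has inflated variance only on channel 3
  ea <- make_var_epochs(12, 5, seed = 21)
  eb <- make_var_epochs(12, 5, boost_ch = 3, boost = 4, seed = 22)
  mod <- csp_fit(ea, eb, band = band_def(5, 100), fs = fs)
  w_last <- mod$W[nrow(mod$W), ]      # maximizes class-B variance
  expect_equal(which.max(abs(w_last)), 3L)

  # identical class distributions: eigenvalues all near 1/2 (no structure)
  ec <- make_var_epochs(12, 5, seed = 23)
  ed <- make_var_epochs(12, 5, seed = 24)
  mod0 <- csp_fit(ec, ed, band = band_def(5, 100), fs = fs)
  expect_true(all(abs(mod0$eigenvalues - 0.5) < 0.1))

  # single-channel input is refused
  e1a <- lapply(1:4, function(i) matrix(rnorm(500), nrow = 1))
  expect_error(csp_fit(e1a, e1a, band = band_def(5, 100), fs = fs),
               "two channels")
})

test_that("the first CSP filter beats random spatial directions", {
  ea <- make_var_epochs(15, 4, boost_ch = 2, boost = 3, seed = 31)
  eb <- make_var_epochs(15, 4, seed = 32)
  band <- band_def(5, 100)
  mod <- csp_fit(ea, eb, band = band, fs = fs)
  filt <- function(e) fdbci:::butter_bandpass(e, band$low, band$high, fs)
  CA <- Reduce(`+`, lapply(ea, function(e) fdbci:::trial_cov(filt(e)))) / 15
  CB <- Reduce(`+`, lapply(eb, function(e) fdbci:::trial_cov(filt(e)))) / 15
  ratio <- function(w) as.numeric((w %*% CA %*% w) / (w %*% (CA + CB) %*% w))
  best <- ratio(mod$W[1, ])
  rnd <- withr::with_seed(33, replicate(1000, {
    w <- rnorm(4); ratio(w / sqrt(sum(w^2)))
  }))
  expect_true(all(rnd <= best + 1e-10))
})

test_that("CSP features are 2p log powers, scale-invariant", {
  ea <- make_var_epochs(10, 6, boost_ch = 1, boost = 2, seed = 41)
  eb <- make_var_epochs(10, 6, seed = 42)
  mod <- csp_fit(ea, eb, band = band_def(5, 100), fs = fs, p = 2)
  f <- csp_features(ea[[1]], mod)
  expect_length(f, 4)

  # epoch-wide scaling cancels in the normalized log power
  expect_equal(csp_features(10 * ea[[1]], mod), f, tolerance = 1e-9)

  expect_error(csp_features(matrix(0, 6, 500), mod), "zero")
  expect_error(csp_features(ea[[1]], mod, p = 4), "invalid p")
})
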