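test_that("delay embedding reproduces the reconstruction layout", {
  # direct substitution: x = 1..5, tau = 1, M = 2
  emb <- delay_embed(1:5, tau = 1, M = 2)
  expect_equal(emb$vectors,
               matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 2))
  expect_equal(emb$Np, 4L)

  # vector-count arithmetic at epoch scale
  emb2 <- delay_embed(rnorm(1500), tau = 50, M = 3)
  expect_equal(emb2$Np, 1400L)
  expect_equal(ncol(emb2$vectors), 3L)

  # M = 1 is the identity
  x <- rnorm(20)
  emb3 <- delay_embed(x, tau = 7, M = 1)
  expect_equal(as.numeric(emb3$vectors), x)

  # too-short epochs are refused with a descriptive error
  expect_error(delay_embed(1:10, tau = 5, M = 3), "too short")
})

test_that("correlation integral counts unordered pairs with H(0) = 0", {
  # two vectors at distance 1
  emb <- delay_embed(c(0, 1), tau = 1, M = 1)
  expect_equal(correlation_integral(emb, 2), 1)
  expect_equal(correlation_integral(emb, 0.5), 0)
  expect_equal(correlation_integral(emb, 1), 0)  # strict inequality

  # three 1-d points {0, 1, 2}: pairs at distances 1, 1, 2
  emb3 <- delay_embed(c(0, 1, 2), tau = 1, M = 1)
  expect_equal(correlation_integral(emb3, 1.5), 2 / 3)

  expect_error(correlation_integral(emb3, -1), "positive")
})

test_that("correlation integral matches the naive double loop exactly", {
  spec <- cd_radius_spec()
  for (seed in 1:5) {
    x <- surrogate_epoch(N = 250, seed = seed)
    for (M in c(2, 4)) {
      tau <- 5
      emb <- delay_embed(x, tau, M)
      radii <- fdbci:::cd_radii(x, tau, M, spec)
      fast <- fdbci:::cpp_corr_curve(x, tau, M, radii^2)
      slow <- vapply(radii, function(r)
        naive_correlation_integral(emb$vectors, r), numeric(1))
      expect_identical(fast, slow)
    }
  }
})

test_that("correlation dimension recovers the dimension of simple sets", {
  # points spread along a line segment: d_c ~ 1
  x <- seq(0, 1, length.out = 300)
  cc <- correlation_dimension(x, tau = 1, M = 2)
  expect_lt(abs(cc$slope - 1), 0.1)
  expect_true(all(diff(cc$values) >= 0))
  expect_true(all(cc$values >= 0 & cc$values <= 1))

  # points filling a planar region: d_c ~ 2 (small-radius scaling window;
  # at larger radii the square's boundary flattens the curve)
  pts <- withr::with_seed(42, cbind(runif(1200), runif(1200)))
  cc2 <- correlation_dimension(pts,
                               radius_spec = cd_radius_spec(lo_q = 0.005,
                                                            hi_q = 0.05))
  expect_lt(abs(cc2$slope - 2), 0.2)

  # identical points with an explicit radius grid: C(r) = 1, slope 0
  const <- matrix(1, nrow = 10, ncol = 2)
  cc3 <- correlation_dimension(const, radius_spec = c(0.5, 1, 2, 4, 8))
  expect_equal(cc3$values, rep(1, 5))
  expect_equal(cc3$slope, 0)

  # ... but a percentile grid cannot be built on a degenerate set
  expect_error(correlation_dimension(rep(2, 100), tau = 1, M = 2),
               "zero-diameter")
})

test_that("gpfd saturates on a periodic orbit and not on white noise", {
  x <- sin(2 * pi * 10 * seq_len(1500) / 500)
  g <- gpfd(x, tau = 12)
  expect_true(g$saturated)
  expect_lt(abs(g$fd - 1), 0.25)
  expect_equal(g$fd, tail(g$dc_trajectory$dc, 1))
  # the stopping rule really held at M_final
  dc <- g$dc_trajectory$dc
  n <- length(dc)
  expect_lt(abs(dc[n] - dc[n - 1]), g$epsilon)

  wn <- withr::with_seed(7, rnorm(1500))
  gw <- gpfd(wn, tau = 50)
  expect_false(gw$saturated)
  # d_c grows with M for noise (checked over the early, well-sampled range)
  traj <- gw$dc_trajectory$dc[1:9]           # M = 2..10
  expect_gt(mean(diff(traj)), 0)
  expect_gt(traj[9], traj[1] + 2)

  expect_error(gpfd(rep(1, 500)), "constant")
})

test_that("gpfd on EEG-like surrogates stops at a moderate embedding", {
  finals <- vapply(1:5, function(s)
    gpfd(surrogate_epoch(seed = s), tau = 50, M_max = 30)$M_final,
    numeric(1))
  expect_true(all(finals >= 5 & finals <= 30))
})

test_that("estimators are invariant to amplitude scaling", {
  x <- surrogate_epoch(seed = 11)
  base_g <- gpfd(x, tau = 50, M_max = 10)
  base_h <- hfd(x)
  for (a in c(2, 10)) {
    expect_equal(gpfd(a * x, tau = 50, M_max = 10)$fd, base_g$fd,
                 tolerance = 1e-9)
    expect_equal(hfd(a * x)$fd, base_h$fd, tolerance = 1e-9)
  }
})

test_that("higuchi curve lengths follow the defining formula", {
  # constant signal: zero length
  expect_equal(higuchi_curve_length(rep(3, 100), m = 1, k = 5), 0)

  # linear ramp with slope a: L_m(k) = a (N-1) / k for every valid (m, k)
  N <- 200; a <- 0.37
  y <- a * seq_len(N)
  for (k in c(1, 3, 7)) {
    for (m in seq_len(k)) {
      expect_equal(higuchi_curve_length(y, m, k), a * (N - 1) / k)
    }
  }

  # k = 1, m = 1: the total variation (normalization factor is unity)
  z <- withr::with_seed(5, rnorm(50))
  expect_equal(higuchi_curve_length(z, 1, 1), sum(abs(diff(z))))

  expect_error(higuchi_curve_length(z, 1, 50), "exceeds")
})

test_that("hfd matches the naive transcription and known dimensions", {
  y <- surrogate_epoch(N = 400, seed = 3)
  expect_equal(hfd(y, kmax = 40)$lengths, naive_higuchi_L(y, 40))

  # noiseless ramp: L(k) proportional to 1/k exactly, so the slope is 1
  expect_equal(hfd(seq_len(1500), kmax = 100)$fd, 1, tolerance = 1e-9)

  # white Gaussian noise: FD ~ 2
  fds <- vapply(1:20, function(s)
    hfd(withr::with_seed(s, rnorm(1500)), kmax = 100)$fd, numeric(1))
  expect_lt(abs(mean(fds) - 2), 0.1)

  expect_error(hfd(rep(1, 500)), "undefined")
  expect_error(hfd(rnorm(100), kmax = 60), "half")
})

test_that("C(r) is monotone and bounded for every embedding", {
  for (seed in 1:3) {
    x <- surrogate_epoch(N = 600, seed = seed)
    for (M in c(2, 5, 8)) {
      cc <- correlation_dimension(x, tau = 20, M = M)
      expect_true(all(cc$values >= 0 & cc$values <= 1))
      expect_true(all(diff(cc$values) >= 0))
    }
  }
})
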