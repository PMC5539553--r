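test_that("knn predictions follow the documented tie-breaks", {
  tr <- matrix(c(0, 1, 2, 10), ncol = 1)
  lab <- c("a", "a", "b", "b")

  # query equal to a training point, K = 1
  expect_equal(knn_predict(tr, lab, 2, K = 1), "b")

  # majority among K = 3: neighbors of 0.6 are {0, 1, 2} -> a, a, b
  expect_equal(knn_predict(tr, lab, 0.6, K = 3), "a")

  # two equidistant opposite-class neighbors, K = 2: smaller mean distance
  tr2 <- matrix(c(-1, 1, -3, 3), ncol = 1)
  lab2 <- c("a", "b", "a", "b")
  # query 0.5: nearest two are 1 (b) and -1 (a); mean dist b = 0.5 < a = 1.5
  expect_equal(knn_predict(tr2, lab2, 0.5, K = 2), "b")
  # query 0: both classes tie exactly -> lower class wins
  expect_equal(knn_predict(tr2, lab2, 0, K = 2), "a")

  expect_error(knn_predict(tr[0, , drop = FALSE], character(0), 1, K = 1),
               "empty")
  expect_error(knn_predict(tr, lab, 1, K = 9), "exceeding")
})

test_that("lda places the boundary between equal-variance classes", {
  tr <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  lab <- rep(c(-1, 1), each = 3)
  expect_equal(lda_fit_predict(tr, lab, 0.5), 1, ignore_attr = TRUE)
  expect_equal(lda_fit_predict(tr, lab, -0.5), -1, ignore_attr = TRUE)

  # class-swapped training data gives complementary predictions
  # (queries off the decision boundary, whose side is a tie convention)
  qs <- matrix(setdiff(seq(-2, 2, by = 0.5), 0), ncol = 1)
  p1 <- lda_fit_predict(tr, lab, qs)
  p2 <- lda_fit_predict(tr, -lab, qs)
  expect_equal(as.numeric(p1), -as.numeric(p2))

  # matches MASS::lda with equal priors on a generic problem
  set.seed(20)
  x <- rbind(matrix(rnorm(60, 0), ncol = 3),
             matrix(rnorm(60, 1.2), ncol = 3))
  y <- rep(0:1, each = 20)
  q <- matrix(rnorm(30, 0.6), ncol = 3)
  ours <- lda_fit_predict(x, y, q)
  mass <- as.integer(as.character(
    predict(MASS::lda(x, grouping = y, prior = c(0.5, 0.5)), q)$class))
  expect_equal(as.integer(ours), mass, ignore_attr = TRUE)

  # singular pooled covariance falls back to shrinkage instead of failing
  xs <- cbind(c(0, 0, 1, 1), c(0, 0, 2, 2))   # duplicated information
  ps <- lda_fit_predict(xs, c(0, 0, 1, 1), c(1, 2))
  expect_equal(as.integer(ps), 1L, ignore_attr = TRUE)
  expect_gt(attr(ps, "shrinkage_used"), 0)
})

test_that("well-separated spherical classes reach perfect LOO accuracy", {
  x <- withr::with_seed(6, rbind(matrix(rnorm(40 * 3), ncol = 3),
                                 matrix(rnorm(40 * 3, mean = 6), ncol = 3)))
  y <- rep(0:1, each = 40)
  expect_equal(loo_cv(x, y, classifier_spec("lda"))$accuracy, 1)
  expect_equal(loo_cv(x, y, classifier_spec("knn"))$accuracy, 1)
})

test_that("loo_cv runs one fold per trial and reassembles its accuracy", {
  x <- withr::with_seed(12, matrix(rnorm(80 * 4), ncol = 4))
  y <- rep(0:1, each = 40)
  rep_ <- loo_cv(x, y, classifier_spec("knn", K = 3))
  expect_equal(rep_$n_folds, 80L)
  expect_equal(nrow(rep_$per_fold), 80L)
  expect_equal(mean(rep_$per_fold$pred == rep_$per_fold$truth),
               rep_$accuracy)
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 1)
  expect_error(loo_cv(x[1:2, ], y[1:2]), "fewer than 3")
})

test_that("label-permuted features classify at chance", {
  x <- withr::with_seed(1, matrix(rnorm(80 * 5), ncol = 5))
  acc <- vapply(1:100, function(s) {
    y <- withr::with_seed(1000 + s, sample(rep(0:1, each = 40)))
    loo_cv(x, y, classifier_spec("knn", K = 1))$accuracy
  }, numeric(1))
  expect_gte(mean(acc >= 0.35 & acc <= 0.65), 0.95)
})

test_that("grid search returns the argmax with smaller-value tie-break", {
  # single candidate: identity
  expect_equal(grid_search(50, function(p) 0.7)$best, 50)

  # the protocol's six-point delay grid produces six accuracy entries
  gs <- grid_search(c(20, 30, 40, 50, 60, 70),
                    function(p) c(0.5, 0.6, 0.8, 0.8, 0.7, 0.6)[p / 10 - 1])
  expect_equal(nrow(gs$table), 6L)
  expect_equal(gs$best, 40)       # 40 and 50 tie at 0.8; smaller wins
  expect_equal(gs$best_value, 0.8)
})

test_that("deterministic pipelines give identical reports on reruns", {
  ses <- gen_session(session_spec(n_channels = 4, epochs_per_class = 8,
                                  seed = 5))
  r1 <- pipeline_evaluate(ses, "hfd", spec = classifier_spec("knn"))
  r2 <- pipeline_evaluate(ses, "hfd", spec = classifier_spec("knn"))
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("nested selection never sees the held-out trial", {
  # on no-effect data, selecting channels on ALL trials (paper-faithful)
  # leaks information and cannot under-perform the nested variant on
  # average
  diffs <- vapply(1:60, function(s) {
    x <- withr::with_seed(300 + s, matrix(rnorm(40 * 8), ncol = 8))
    y <- rep(0:1, each = 20)
    nested <- loo_cv(x, y, classifier_spec("knn"), select_d = 2)$accuracy
    tabsel <- select_channels(fisher_scores(feature_table(x, y)), 2)
    faithful <- loo_cv(x[, tabsel, drop = FALSE], y,
                       classifier_spec("knn"))$accuracy
    faithful - nested
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("channel policies drive the pipeline evaluator", {
  ses <- gen_session(session_spec(n_channels = 6, epochs_per_class = 10,
                                  informative_channels = c("F3", "FZ"),
                                  hurst_shift = 0.3, seed = 31))
  r_all <- pipeline_evaluate(ses, "hfd", "all", classifier_spec("knn"))
  expect_equal(r_all$channel_config, "all")
  r_top <- pipeline_evaluate(ses, "hfd", list(mode = "top", d = 2),
                             classifier_spec("knn"))
  expect_equal(r_top$channel_config, "top2")
  expect_gte(r_top$accuracy, 0.8)
  r_pf <- pipeline_evaluate(ses, "hfd", list(mode = "top", d = 2),
                            classifier_spec("knn"), paper_faithful = TRUE)
  expect_equal(r_pf$n_folds, 20L)

  # CSP needs at least two channels
  expect_error(pipeline_evaluate(ses, "csp", list(mode = "top", d = 1)),
               "two channels")
})

test_that("csp pipeline separates a planted variance contrast", {
  # class-dependent band-limited variance on two channels
  ses <- gen_session(session_spec(n_channels = 5, epochs_per_class = 12,
                                  informative_channels = c("F3", "FZ"),
                                  hurst_shift = 0,
                                  band_power_shift = list(
                                    band = band_def(13, 30), ratio = 9),
                                  seed = 77))
  r <- pipeline_evaluate(ses, "csp", "all", classifier_spec("lda"), p = 1)
  expect_gte(r$accuracy, 0.85)
})
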