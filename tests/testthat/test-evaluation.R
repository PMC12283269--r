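test_that("confusion metrics follow the printed formulas", {
  cm <- classification_metrics(list(TP = 5, TN = 3, FP = 1, FN = 1))
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$precision, 5 / 6)
  expect_equal(cm$recall, 5 / 6)
  expect_equal(cm$specificity, 0.75)
  expect_length(cm$degenerate, 0L)
  # never-positive classifier: precision 0 with a degenerate flag
  d <- classification_metrics(list(TP = 0, TN = 4, FP = 0, FN = 2))
  expect_equal(d$precision, 0)
  expect_true("precision" %in% d$degenerate)
  perfect <- classification_metrics(confusion_counts(c(0, 1, 1, 0), c(0, 1, 1, 0)))
  expect_equal(unlist(perfect[1:4]), c(accuracy = 1, precision = 1,
                                       recall = 1, specificity = 1))
  expect_error(classification_metrics(list(TP = -1, TN = 0, FP = 0, FN = 0)),
               "nonnegative")
})

test_that("rank AUC matches enumeration, ties, and the trapezoid oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  # pos {0.9, 0.4}, neg {0.5, 0.1}: 3 of 4 pairs ordered correctly
  expect_equal(auc_rank(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_rank(1:3, c(1, 1, 1)), "positive and one negative")
  # invariance under strictly monotone transforms
  set.seed(1)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(auc_rank(s, y), auc_rank(exp(s), y))
  # 500 random instances against trapezoidal ROC integration
  set.seed(2)
  worst <- 0
  for (i in 1:500) {
    n <- sample(4:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))  # induce ties
    worst <- max(worst, abs(auc_rank(s, y) - auc_trapezoid(s, y)))
  }
  expect_lt(worst, 1e-9)
})

test_that("the score is the mean of the five indicators", {
  expect_equal(score(list(accuracy = 0.71, precision = 0.86, recall = 0.54,
                          specificity = 0.88, auc = 0.90)), 0.778)
  expect_equal(score(list(accuracy = 0.58, precision = 0.67, recall = 0.55,
                          specificity = 0.50, auc = 0.52)), 0.564)
  expect_equal(score(list(accuracy = 1, precision = 1, recall = 1,
                          specificity = 1, auc = 1)), 1)
  expect_error(score(list(accuracy = 1, precision = 1)), "missing metric")
  ms <- metric_set(c(1, 0, 1, 0), c(1, 0, 0, 0), c(0.9, 0.2, 0.4, 0.1))
  expect_equal(ms$score,
               mean(c(ms$accuracy, ms$precision, ms$recall, ms$specificity,
                      ms$auc)))
})

test_that("subsampled evaluation is a seeded 10 x 10 protocol", {
  co <- generate_cohort(tiny_spec(seed = 41))
  sp <- split_cohort(co, seed = 41)
  m <- train_model(build_model("cnn", seed = 1), sp$train, quick_cfg(epochs = 1L))
  out <- subsample_evaluate(m, sp$test, reps = 10L, seed = 3)
  expect_equal(nrow(out$raw), 100L)
  expect_equal(nrow(out$summary), 10L)
  full <- out$raw[out$raw$fraction == 1, ]
  expect_equal(length(unique(full$accuracy)), 1L)
  ev <- evaluate_model(m, sp$test)
  expect_equal(full$accuracy[1], ev$metrics$accuracy)
  out2 <- subsample_evaluate(m, sp$test, reps = 10L, seed = 3)
  expect_identical(out$raw, out2$raw)
})

test_that("model comparison is a symmetric two-sided t-test", {
  a <- c(0.9, 0.91, 0.89, 0.9)
  b <- c(0.5, 0.51, 0.49, 0.5)
  res <- compare_models(a, b)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, compare_models(b, a)$p_value)
  expect_equal(res$statistic, -compare_models(b, a)$statistic)
  expect_equal(compare_models(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  # oracle: Welch statistic computed directly
  tt <- stats::t.test(a, b)
  expect_equal(res$statistic, unname(tt$statistic))
})

test_that("silhouette matches the formula and the brute-force oracle", {
  # two tight 1-D clusters: {0, 0.1} vs {10, 10.1}
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(0, 0, 1, 1)
  # per point: a = 0.1; b = mean distance to the two far points
  hand <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                 (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(silhouette_score(pts, lab), hand, tolerance = 1e-12)
  expect_gt(silhouette_score(pts, lab), 0.98)
  expect_equal(silhouette_score(matrix(1, 6, 2), rep(c(0, 1), 3)), 0)
  # perfectly interleaved labels score negative
  inter <- matrix(c(0, 1, 2, 3), ncol = 1)
  expect_lt(silhouette_score(inter, c(0, 1, 0, 1)), 0)
  expect_error(silhouette_score(matrix(rnorm(10), 5), rep(1, 5)), "2 clusters")
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    p <- matrix(rnorm(n * 2), n)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(silhouette_score(p, l), silhouette_brute_force(p, l),
                 tolerance = 1e-10)
  }
})

test_that("embedding plots are written and inputs validated", {
  f <- file.path(tempdir(), "emb.png")
  pts <- matrix(rnorm(20), 10, 2)
  export_embedding_plot(pts, rep(c(0, 1), 5), f)
  expect_true(file.exists(f))
  expect_gt(file.info(f)$size, 0)
  unlink(f)
  expect_error(export_embedding_plot(matrix(rnorm(30), 10, 3),
                                     rep(0:1, 5), f), "2-dimensional")
  expect_error(export_embedding_plot(matrix(0, 0, 2), integer(0), f),
               "no points")
})
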