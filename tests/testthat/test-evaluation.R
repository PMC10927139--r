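test_that("subset accuracy is high on separable data and seed-stable", {
  ds <- separable_dataset(n = 40, p = 10, n_signal = 3, delta = 5, seed = 2)
  proto <- eval_protocol("svm", cv_folds = 5, cv_seed = 4)
  acc <- evaluate_subset(ds, 1:3, proto)
  expect_gte(acc, 0.95)
  expect_identical(acc, evaluate_subset(ds, 1:3, proto))
  # invariant to feature order within the subset
  expect_equal(acc, evaluate_subset(ds, c(3, 1, 2), proto))
  expect_error(evaluate_subset(ds, integer(0), proto), "non-empty")
  expect_error(evaluate_subset(ds, 99, proto), "invalid")
})

test_that("KNN backend matches SVM on cleanly separable data", {
  ds <- separable_dataset(n = 40, p = 10, n_signal = 3, delta = 6, seed = 3)
  acc_knn <- evaluate_subset(ds, 1:3, eval_protocol("knn", cv_folds = 4,
                                                    cv_seed = 1))
  expect_gte(acc_knn, 0.95)
})

test_that("cv_folds beyond the smallest class count is rejected", {
  ds <- expression_dataset(matrix(rnorm(24), 8, 3), c(1, 1, 1, 1, 1, 1, 2, 2))
  expect_error(evaluate_subset(ds, 1:2, eval_protocol("svm", cv_folds = 3)),
               "smallest class")
})

test_that("filter scores behave as expected on engineered features", {
  y <- rep(1:2, each = 10)
  X <- cbind(perfect = as.numeric(y == 2) * 10,
             constant = rep(1, 20),
             noise = c(0.3, -0.8, 0.5, -0.1, 0.9, -0.4, 0.2, -0.6, 0.7, -0.2,
                       0.1, -0.9, 0.4, -0.3, 0.6, -0.5, 0.8, -0.7, 0.05, -0.15))
  ds <- expression_dataset(X, y)
  for (m in c("ig", "chi2", "pearson")) {
    s <- feature_scores(ds, m)
    expect_equal(which.max(s), 1L)     # separating feature dominates
    expect_equal(s[[2]], 0)            # constant scores zero
    expect_true(all(is.finite(s)) && all(s >= 0))
  }
})

test_that("chi-square scores match stats::chisq.test on random tables", {
  set.seed(5)
  for (i in 1:20) {
    tab <- random_count_table(max_bins = 4, max_classes = 3, max_n = 60)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    ex <- expand_table(tab)
    got <- iggpso:::chi2_statistic(ex$bins, ex$labels)
    want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
  # hand case: diagonal 2x2 with counts 10/10
  ex <- expand_table(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(iggpso:::chi2_statistic(ex$bins, ex$labels), 20.0)
})

test_that("filter threshold keeps half of the strictly-positive scorers", {
  y <- rep(1:2, each = 10)
  set.seed(6)
  X <- cbind(matrix(rep(as.numeric(y == 2), 6), ncol = 6) +
               matrix(rnorm(120, sd = 0.1), ncol = 6),
             matrix(rep(c(1, 2), 40), nrow = 20))  # 4 two-valued label-independent cols
  ds <- expression_dataset(X, y)
  s <- feature_scores(ds, "ig")
  n_inf <- sum(s > 0)
  sel <- filter_select(ds, "ig")
  expect_equal(length(sel), ceiling(n_inf / 2))
  # independent sort-and-slice oracle
  oracle <- sort(order(-s, seq_along(s))[seq_len(ceiling(n_inf / 2))])
  expect_equal(sel, oracle)
  # all-informative with distinct scores: top half by score
  expect_true(all(sel %in% which(s > 0)))
})

test_that("degenerate inputs to the filters are rejected or scored zero", {
  ds <- expression_dataset(matrix(rep(c(1, 5), each = 6), 6, 2), rep(1:2, 3))
  expect_equal(feature_scores(ds, "pearson"), c(0, 0))
  expect_error(filter_select(ds, "pearson"), "no informative")
})

test_that("pearson scores use one-vs-rest for multiclass labels", {
  set.seed(8)
  y <- rep(1:3, each = 8)
  x <- as.numeric(y == 2) + rnorm(24, sd = 0.05)
  ds <- expression_dataset(cbind(x, rnorm(24)), y)
  s <- feature_scores(ds, "pearson")
  expect_gt(s[1], 0.9)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("hybrid selection composes filter and wrapper", {
  ds <- separable_dataset(n = 30, p = 14, n_signal = 3, delta = 5, seed = 12)
  cfg <- gpso_config(seed = 9, swarm_size = 5, max_iter = 5, patience = 2)
  proto <- eval_protocol("knn", cv_folds = 3, cv_seed = 3, k_neighbors = 3)
  res <- hybrid_select(ds, "ig", config = cfg, protocol = proto)
  expect_true(all(res$selected %in% res$filter_survivors))
  expect_equal(res$fs, length(res$selected))
  # survivors are the filter's own output
  expect_equal(res$filter_survivors, filter_select(ds, "ig"))
})

test_that("a single filter survivor is returned as a singleton", {
  y <- rep(1:2, each = 8)
  X <- cbind(sig = as.numeric(y == 2),
             matrix(rep(c(2, 2, 2, 2), 16), nrow = 16))  # constants
  ds <- expression_dataset(X, y)
  cfg <- gpso_config(seed = 1, swarm_size = 3, max_iter = 3, patience = 1)
  proto <- eval_protocol("knn", cv_folds = 2, cv_seed = 1, k_neighbors = 3)
  res <- hybrid_select(ds, "ig", config = cfg, protocol = proto)
  expect_equal(res$selected, 1L)
})

test_that("benchmark emits ACC/FS tables with a correct average row", {
  ds1 <- separable_dataset(n = 24, p = 8, seed = 21)
  ds2 <- separable_dataset(n = 24, p = 8, seed = 22)
  algs <- list(
    all = function(ds, pr) seq_len(ncol(ds$expression)),
    ig = function(ds, pr) filter_select(ds, "ig")
  )
  proto <- list(knn = eval_protocol("knn", cv_folds = 3, cv_seed = 2,
                                    k_neighbors = 3))
  res <- benchmark(list(a = ds1, b = ds2), algs, proto)
  expect_equal(dim(res$acc$values), c(2L, 2L))
  expect_equal(unname(unlist(res$acc_df["Average", ])),
               unname(colMeans(res$acc$values)))
  expect_equal(unname(unlist(res$fs_df["Average", ])),
               unname(colMeans(res$fs$values)))
  expect_equal(res$fs$values[, "all"], rep(8, 2))
  # round trip through the score-table CSV layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(res$acc, path)
  back <- read_score_table(path)
  expect_equal(unname(back$values), unname(res$acc$values), tolerance = 1e-6)
  expect_equal(back$row_direction, res$acc$row_direction)
})
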