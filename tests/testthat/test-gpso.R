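test_that("swarm initialization has correct shapes, ranges, and determinism", {
  cfg <- gpso_config(swarm_size = 5, v_max = 4, seed = 1)
  set.seed(123)
  sw <- init_swarm(10, cfg)
  expect_equal(dim(sw$position), c(5L, 10L))
  expect_equal(dim(sw$velocity), c(5L, 10L))
  expect_true(all(sw$position %in% c(0L, 1L)))
  expect_true(all(abs(sw$velocity) <= 4))
  expect_true(all(rowSums(sw$position) >= 1))
  set.seed(123)
  sw2 <- init_swarm(10, cfg)
  expect_identical(sw, sw2)
  # degenerate pool: repair forces the single bit on
  set.seed(99)
  sw1 <- init_swarm(1, cfg)
  expect_true(all(sw1$position == 1L))
  expect_error(gpso_config(swarm_size = 1), "swarm_size")
})

test_that("velocity update follows the inertia/attraction form with clamping", {
  cfg <- gpso_config(w = 1, c1 = 0, c2 = 0, v_max = 10)
  v <- c(0.5, -2, 3)
  expect_equal(update_velocity(v, c(1, 0, 1), c(0, 1, 1), c(1, 1, 0), cfg,
                               r1 = 0.3, r2 = 0.8), v)
  # x = pbest = gbest leaves only inertia
  cfg2 <- gpso_config(w = 0.6, c1 = 2, c2 = 2, v_max = 10)
  x <- c(1, 0)
  expect_equal(update_velocity(c(2, -2), x, x, x, cfg2, r1 = 0.9, r2 = 0.1),
               0.6 * c(2, -2))
  # scalar hand case: 0.5*1 + 1*0.5*2 + 1*0.5*4 = 3.5
  cfg3 <- gpso_config(w = 0.5, c1 = 1, c2 = 1, v_max = 10)
  expect_equal(update_velocity(1, 0, 2, 4, cfg3, r1 = 0.5, r2 = 0.5), 3.5)
  # clamping
  cfg4 <- gpso_config(w = 1, c1 = 10, c2 = 10, v_max = 2)
  out <- update_velocity(c(5, -5), c(0, 1), c(1, 0), c(1, 0), cfg4,
                         r1 = 1, r2 = 1)
  expect_true(all(abs(out) <= 2))
})

test_that("sigmoid transfer saturates and is deterministic under a seed", {
  set.seed(4)
  expect_equal(update_position(rep(50, 8)), rep(1L, 8))
  set.seed(4)
  b1 <- update_position(c(0.3, -0.2, 1.5, -4))
  set.seed(4)
  b2 <- update_position(c(0.3, -0.2, 1.5, -4))
  expect_identical(b1, b2)
  # all-zero repair picks the largest-velocity dimension
  set.seed(1)
  b <- update_position(c(-60, -50, -70))
  expect_equal(b, c(0L, 1L, 0L))
})

test_that("out-group fitness trades accuracy against subset size", {
  expect_equal(out_group_fitness(0.73, 5, 100, lambda = 1), 0.73)
  expect_equal(out_group_fitness(0.8, 20, 100, lambda = 0.5), 0.3)
  expect_equal(out_group_fitness(1, 100, 100, lambda = 0), -1)
  expect_error(out_group_fitness(0.5, 1, 0), "total_features")
  expect_error(out_group_fitness(0.5, 5, 4), "subset_size")
})

test_that("in-group fitness is the cross-validated accuracy of the subset", {
  ds <- separable_dataset(n = 24, p = 6, n_signal = 2, delta = 6)
  proto <- eval_protocol("knn", cv_folds = 3, cv_seed = 2, k_neighbors = 3)
  rec <- in_group_fitness(c(1L, 1L, 0L), active_pool = 1:3, ds, proto)
  expect_equal(rec$in_fitness, rec$acc)
  expect_equal(rec$subset_size, 2L)
  expect_equal(rec$acc, 1.0)
  expect_error(in_group_fitness(c(0L, 0L), 1:2, ds, proto), "1 feature")
})

test_that("permuted labels give near-chance in-group fitness", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rep(1:2, each = n / 2)[sample(n)]
  ds <- expression_dataset(X, y)
  proto <- eval_protocol("svm", cv_folds = 5, cv_seed = 3)
  acc <- evaluate_subset(ds, 1:8, proto)
  # binomial null around the majority rate 0.5 with 3 SDs of slack
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
})

test_that("grouped search recovers a planted perfect feature in group 1", {
  ds <- separable_dataset(n = 30, p = 15, n_signal = 2, delta = 8, seed = 8)
  ranked <- rank_features(ds)
  expect_true(all(ranked$order[1:2] %in% 1:2))  # signal tops the ranking
  groups <- partition_features(ranked, 3)
  cfg <- gpso_config(seed = 5, swarm_size = 6, max_iter = 8, patience = 3)
  proto <- eval_protocol("knn", cv_folds = 3, cv_seed = 1, k_neighbors = 3)
  res <- run_gpso(groups, ds, cfg, proto)
  expect_true(any(res$selected %in% 1:2))
  expect_equal(res$acc, 1.0)
  expect_equal(res$fs, length(res$selected))
})

test_that("identical seed and config reproduce the selection exactly", {
  ds <- separable_dataset(n = 24, p = 10, seed = 13)
  groups <- partition_features(rank_features(ds), 2)
  cfg <- gpso_config(seed = 42, swarm_size = 5, max_iter = 6, patience = 2)
  proto <- eval_protocol("knn", cv_folds = 2, cv_seed = 6, k_neighbors = 3)
  r1 <- run_gpso(groups, ds, cfg, proto)
  r2 <- run_gpso(groups, ds, cfg, proto)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$acc, r2$acc)
})

test_that("fitness cache is transparent", {
  ds <- separable_dataset(n = 24, p = 10, seed = 14)
  groups <- partition_features(rank_features(ds), 2)
  proto <- eval_protocol("knn", cv_folds = 2, cv_seed = 6, k_neighbors = 3)
  r_cache <- run_gpso(groups, ds, gpso_config(seed = 3, swarm_size = 5,
                                              max_iter = 5, patience = 2,
                                              cache = TRUE), proto)
  r_plain <- run_gpso(groups, ds, gpso_config(seed = 3, swarm_size = 5,
                                              max_iter = 5, patience = 2,
                                              cache = FALSE), proto)
  expect_identical(r_cache$selected, r_plain$selected)
  expect_identical(r_cache$history, r_plain$history)
})

test_that("gbest fitness is non-decreasing within each phase and the final
           subset dominates every phase champion under the out-group objective", {
  ds <- separable_dataset(n = 30, p = 18, n_signal = 3, seed = 4)
  groups <- partition_features(rank_features(ds), 4)
  cfg <- gpso_config(seed = 7, swarm_size = 5, max_iter = 6, patience = 2,
                     lambda = 0.8)
  proto <- eval_protocol("knn", cv_folds = 3, cv_seed = 2, k_neighbors = 3)
  res <- run_gpso(groups, ds, cfg, proto)
  traj <- trajectory(res)
  for (ph in unique(traj$phase)) {
    expect_true(all(diff(traj$gbest_in_fitness[traj$phase == ph]) >= 0))
  }
  final_out <- out_group_fitness(res$acc, res$fs, 18, cfg$lambda)
  for (p in res$phases) {
    expect_gte(final_out + 1e-12, p$out_fitness)
  }
  # active pool grows by whole groups
  expect_equal(sort(unique(traj$active_pool_size)),
               cumsum(lengths(groups$groups))[unique(traj$phase)])
})

test_that("single-group search is trajectory-identical to a plain binary PSO", {
  ds <- separable_dataset(n = 24, p = 12, n_signal = 2, seed = 31)
  cfg <- gpso_config(seed = 17, swarm_size = 6, max_iter = 8, patience = 3,
                     lambda = 1, cache = FALSE)
  proto <- eval_protocol("knn", cv_folds = 3, cv_seed = 9, k_neighbors = 3)
  oracle <- plain_bpso_oracle(ds, cfg, proto)
  res <- pso_select(ds, cfg, proto)
  expect_equal(trajectory(res), oracle$history)
  expect_identical(res$selected, oracle$selected)
  expect_equal(res$acc, oracle$acc)
})
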