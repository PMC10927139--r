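# Independent oracles and small fixtures shared across tests.

# --- entropy oracles: direct sums over a contingency table of counts --------

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# H(C | bins) from a bins x classes count matrix, cell-by-cell
oracle_conditional_entropy <- function(tab) {
  n <- sum(tab)
  total <- 0
  for (b in seq_len(nrow(tab))) {
    for (cl in seq_len(ncol(tab))) {
      pj <- tab[b, cl] / n
      if (pj > 0) total <- total - pj * log2(tab[b, cl] / sum(tab[b, ]))
    }
  }
  total
}

oracle_joint_entropy <- function(tab) oracle_entropy(as.vector(tab))

# expand a bins x classes count table into (bins, labels) vectors
expand_table <- function(tab) {
  bins <- integer(0); labels <- integer(0)
  for (b in seq_len(nrow(tab))) {
    for (cl in seq_len(ncol(tab))) {
      bins <- c(bins, rep(b, tab[b, cl]))
      labels <- c(labels, rep(cl, tab[b, cl]))
    }
  }
  list(bins = bins, labels = labels)
}

random_count_table <- function(max_bins = 6, max_classes = 4, max_n = 40) {
  nb <- sample(2:max_bins, 1)
  m <- sample(2:max_classes, 1)
  n <- sample((nb * m):max_n, 1)
  tab <- matrix(0L, nb, m)
  idx <- cbind(sample(nb, n, replace = TRUE), sample(m, n, replace = TRUE))
  for (i in seq_len(n)) tab[idx[i, 1], idx[i, 2]] <- tab[idx[i, 1], idx[i, 2]] + 1L
  tab
}

# --- small datasets ----------------------------------------------------------

# two well-separated Gaussian classes; first `n_signal` features informative
separable_dataset <- function(n = 30, p = 12, n_signal = 3, delta = 4, seed = 5) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    y <- rep(1:2, length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(n_signal)) X[, j] <- X[, j] + delta * (y - 1.5)
    expression_dataset(X, paste0("c", y))
  })
}

# --- plain binary PSO oracle -------------------------------------------------
# An independent re-implementation of the single-pool search loop, consuming
# the RNG stream in the documented order: init draws per particle (bits,
# velocities, optional repair index), then per iteration and particle scalar
# r1, r2 followed by one transfer uniform per dimension. Fitness is the
# public evaluate_subset(). Used to check that the grouped search with one
# group reduces exactly to a plain binary PSO.
plain_bpso_oracle <- function(dataset, config, protocol) {
  p <- ncol(dataset$expression)
  s <- config$swarm_size
  sig <- function(v) 1 / (1 + exp(-v))
  set.seed(config$seed)
  pos <- matrix(0L, s, p); vel <- matrix(0, s, p)
  for (i in seq_len(s)) {
    pos[i, ] <- as.integer(runif(p) < 0.5)
    vel[i, ] <- runif(p, -config$v_max, config$v_max)
    if (!any(pos[i, ] == 1L)) pos[i, sample.int(p, 1)] <- 1L
  }
  pbest <- pos; pbest_fit <- rep(-Inf, s)
  gbest <- pos[1, ]; gbest_fit <- -Inf
  stagnation <- 0L
  hist <- NULL
  for (iter in seq_len(config$max_iter)) {
    improved <- FALSE
    for (i in seq_len(s)) {
      f <- evaluate_subset(dataset, which(pos[i, ] == 1L), protocol)
      if (f > pbest_fit[i]) { pbest_fit[i] <- f; pbest[i, ] <- pos[i, ] }
      if (f > gbest_fit) { gbest_fit <- f; gbest <- pos[i, ]; improved <- TRUE }
    }
    stagnation <- if (improved) 0L else stagnation + 1L
    hist <- rbind(hist, data.frame(phase = 1L, iteration = iter,
                                   gbest_in_fitness = gbest_fit,
                                   active_pool_size = p,
                                   gbest_subset_size = sum(gbest)))
    if (stagnation >= config$patience || iter >= config$max_iter) break
    for (i in seq_len(s)) {
      r1 <- runif(1); r2 <- runif(1)
      v <- config$w * vel[i, ] + config$c1 * r1 * (pbest[i, ] - pos[i, ]) +
        config$c2 * r2 * (gbest - pos[i, ])
      vel[i, ] <- pmin(pmax(v, -config$v_max), config$v_max)
      b <- as.integer(runif(p) < sig(vel[i, ]))
      if (!any(b == 1L)) b[which.max(vel[i, ])] <- 1L
      pos[i, ] <- b
    }
  }
  list(selected = which(gbest == 1L), acc = gbest_fit, history = hist)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "iggpso")
}
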