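# Grouping binary particle swarm search.
#
# The swarm searches an "active pool" of features that starts as the first
# (highest-IG) group. Within a pool phase the swarm maximizes in-group fitness
# (cross-validated accuracy, Eq. "fitness = ACC"). When the global best is
# unimproved for `patience` consecutive iterations and groups remain, the next
# group's features are appended to the pool: existing particles are extended
# with fresh random bits and velocities in the new dimensions while personal
# and global bests are zero-extended, preserving learned structure but
# restoring diversity. At the end of every phase the phase champion is scored
# by the out-group objective lambda*ACC - (1-lambda)*|S|/p, and the best
# phase champion under that objective is the final selection.

#' Configuration for the grouping binary PSO
#'
#' @param w Inertia weight (default 0.7).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2.0).
#' @param v_max Velocity clamp, applied per dimension (default 6).
#' @param swarm_size Particles in the swarm (>= 2, default 20).
#' @param max_iter Maximum iterations per active-pool phase (default 30).
#' @param lambda Out-group trade-off weight in `[0, 1]`; 1 scores accuracy
#'   only, 0 scores subset size only (default 0.9).
#' @param patience Consecutive non-improving iterations before the next group
#'   is appended (>= 1, default 5).
#' @param seed RNG seed for the swarm (default 1).
#' @param cache Reuse fitness values for repeated identical subsets
#'   (transparent: results are unchanged with the cache disabled; default
#'   `TRUE`).
#' @return An object of class `gpso_config`.
#' @export
gpso_config <- function(w = 0.7, c1 = 2.0, c2 = 2.0, v_max = 6,
                        swarm_size = 20, max_iter = 30, lambda = 0.9,
                        patience = 5, seed = 1, cache = TRUE) {
  if (lambda < 0 || lambda > 1) stop_validation("lambda must be in [0, 1]")
  if (v_max <= 0) stop_validation("v_max must be > 0")
  if (swarm_size < 2) stop_validation("swarm_size must be >= 2")
  if (patience < 1) stop_validation("patience must be >= 1")
  if (max_iter < 1) stop_validation("max_iter must be >= 1")
  structure(list(w = w, c1 = c1, c2 = c2, v_max = v_max,
                 swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter), lambda = lambda,
                 patience = as.integer(patience), seed = as.integer(seed),
                 transfer = "sigmoid", cache = isTRUE(cache)),
            class = "gpso_config")
}

#' Initialize a swarm over an active pool
#'
#' Each position bit is set independently with probability 0.5 and each
#' velocity is uniform in `[-v_max, v_max]`; an all-zero position is repaired
#' by setting one uniformly chosen bit. Personal bests start at the initial
#' positions with unset (-Inf) fitness; the global best placeholder is
#' particle 1 until the first evaluation.
#'
#' Draws from the current RNG stream: per particle, `pool_size` position
#' uniforms, then `pool_size` velocity uniforms, then (only on repair) one
#' index draw.
#'
#' @param pool_size Number of features in the active pool (>= 1).
#' @param config A [gpso_config()].
#' @return A `swarm_state` list: `position`, `velocity`, `pbest` (matrices,
#'   one row per particle), `pbest_fitness`, `gbest`, `gbest_fitness`,
#'   `stagnation`.
#' @export
init_swarm <- function(pool_size, config = gpso_config()) {
  if (pool_size < 1) stop_validation("pool_size must be >= 1")
  s <- config$swarm_size
  position <- matrix(0L, s, pool_size)
  velocity <- matrix(0, s, pool_size)
  for (i in seq_len(s)) {
    position[i, ] <- as.integer(stats::runif(pool_size) < 0.5)
    velocity[i, ] <- stats::runif(pool_size, -config$v_max, config$v_max)
    if (sum(position[i, ]) == 0) {
      position[i, sample.int(pool_size, 1)] <- 1L
    }
  }
  structure(list(position = position, velocity = velocity,
                 pbest = position, pbest_fitness = rep(-Inf, s),
                 gbest = position[1, ], gbest_fitness = -Inf,
                 stagnation = 0L),
            class = "swarm_state")
}

#' Velocity update for one particle
#'
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with scalar
#' `r1, r2 ~ U(0,1)` drawn fresh per particle per iteration, clamped to
#' `[-v_max, v_max]`.
#'
#' @param velocity,position,pbest_position,gbest_position Numeric vectors of
#'   equal length.
#' @param config A [gpso_config()].
#' @param r1,r2 Optional fixed uniforms (drawn from the RNG stream when
#'   `NULL`).
#' @return Clamped new velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest_position,
                            gbest_position, config = gpso_config(),
                            r1 = NULL, r2 = NULL) {
  r1 <- r1 %||% stats::runif(1)
  r2 <- r2 %||% stats::runif(1)
  v <- config$w * velocity +
    config$c1 * r1 * (pbest_position - position) +
    config$c2 * r2 * (gbest_position - position)
  pmin(pmax(v, -config$v_max), config$v_max)
}

#' Binary position update via the sigmoid transfer function
#'
#' Each bit becomes 1 with probability `1 / (1 + exp(-v))`. An all-zero
#' result is repaired deterministically by setting the dimension with the
#' largest velocity. Draws `length(velocity)` uniforms from the RNG stream.
#'
#' @param velocity Updated velocity vector.
#' @return Integer bit vector with at least one set bit.
#' @export
update_position <- function(velocity) {
  bits <- as.integer(stats::runif(length(velocity)) < 1 / (1 + exp(-velocity)))
  if (sum(bits) == 0) bits[which.max(velocity)] <- 1L
  bits
}

#' In-group fitness of a position: cross-validated accuracy
#'
#' @param position Bit vector over the active pool (>= 1 set bit).
#' @param active_pool Integer feature indices the bits refer to.
#' @param dataset An [expression_dataset()].
#' @param protocol An [eval_protocol()].
#' @return A list (`fitness_record`): `acc`, `subset_size`, `in_fitness`
#'   (= `acc`).
#' @export
in_group_fitness <- function(position, active_pool, dataset,
                             protocol = eval_protocol()) {
  if (sum(position) == 0) stop_validation("position must select >= 1 feature")
  subset <- active_pool[position == 1L]
  acc <- evaluate_subset(dataset, subset, protocol)
  structure(list(acc = acc, subset_size = length(subset), in_fitness = acc),
            class = "fitness_record")
}

#' Out-group fitness: accuracy traded against subset size
#'
#' `lambda * acc - (1 - lambda) * subset_size / total_features`.
#'
#' @param acc Accuracy in `[0, 1]`.
#' @param subset_size Selected feature count (`1 <= subset_size <=
#'   total_features`).
#' @param total_features Total feature count (> 0).
#' @param lambda Trade-off weight in `[0, 1]`.
#' @return Out-group fitness value.
#' @export
out_group_fitness <- function(acc, subset_size, total_features, lambda = 0.9) {
  if (total_features <= 0) stop_validation("total_features must be > 0")
  if (subset_size < 1 || subset_size > total_features) {
    stop_validation("subset_size must be in [1, total_features]")
  }
  lambda * acc - (1 - lambda) * subset_size / total_features
}

#' Grouping binary particle swarm feature selection
#'
#' Runs the grouped wrapper search over IG-ranked feature groups (see module
#' overview at the top of this file). With a single group the trajectory is
#' exactly that of a plain binary PSO under the same seed.
#'
#' @param groups A `feature_groups` object from [partition_features()].
#' @param dataset An [expression_dataset()].
#' @param config A [gpso_config()].
#' @param protocol An [eval_protocol()].
#' @return An object of class `selection_result`: `selected` (feature
#'   indices of the best phase champion under the out-group objective), `acc`,
#'   `fs`, `feature_ids`, `ig_values`, `group_index`, `history` (per-iteration
#'   gbest trace), `phases` (per-phase out-group records), `config_snapshot`,
#'   `seed`.
#' @export
run_gpso <- function(groups, dataset, config = gpso_config(),
                     protocol = eval_protocol()) {
  stopifnot(inherits(groups, "feature_groups"))
  if (groups$k < 1 || any(lengths(groups$groups) == 0)) {
    stop_validation("groups must be a non-empty exact partition")
  }
  total_features <- ncol(dataset$expression)
  evaluator <- make_evaluator(dataset, protocol, cache = config$cache)
  rank_pos <- match(seq_len(total_features), groups$order)  # feature -> rank

  set.seed(config$seed)
  active_pool <- groups$groups[[1]]
  consumed <- 1L
  swarm <- init_swarm(length(active_pool), config)
  s <- config$swarm_size

  history <- list()
  phases <- list()
  best <- NULL  # global out-group best across phases
  phase <- 1L
  iter_in_phase <- 0L

  repeat {
    iter_in_phase <- iter_in_phase + 1L
    # evaluate, update pbest/gbest (strict improvement; first-found wins ties)
    improved <- FALSE
    for (i in seq_len(s)) {
      bits <- swarm$position[i, ]
      fit <- evaluator(active_pool[bits == 1L])
      if (fit > swarm$pbest_fitness[i]) {
        swarm$pbest_fitness[i] <- fit
        swarm$pbest[i, ] <- bits
      }
      if (fit > swarm$gbest_fitness) {
        swarm$gbest_fitness <- fit
        swarm$gbest <- bits
        improved <- TRUE
      }
    }
    swarm$stagnation <- if (improved) 0L else swarm$stagnation + 1L
    history[[length(history) + 1L]] <- data.frame(
      phase = phase, iteration = iter_in_phase,
      gbest_in_fitness = swarm$gbest_fitness,
      active_pool_size = length(active_pool),
      gbest_subset_size = sum(swarm$gbest))

    phase_over <- swarm$stagnation >= config$patience ||
      iter_in_phase >= config$max_iter

    if (phase_over) {
      # out-group scoring of the phase champion
      subset <- active_pool[swarm$gbest == 1L]
      out_fit <- out_group_fitness(swarm$gbest_fitness, length(subset),
                                   total_features, config$lambda)
      phases[[phase]] <- list(phase = phase, subset = subset,
                              acc = swarm$gbest_fitness,
                              subset_size = length(subset),
                              out_fitness = out_fit,
                              pool_size = length(active_pool))
      if (is.null(best) || out_fit > best$out_fitness) {
        phases[[phase]]$is_best <- TRUE
        best <- phases[[phase]]
      }
      if (consumed >= groups$k) break
      # expand: append the next group, extend particles with fresh randomness
      consumed <- consumed + 1L
      new_idx <- groups$groups[[consumed]]
      d <- length(new_idx)
      new_pos <- matrix(0L, s, d)
      new_vel <- matrix(0, s, d)
      for (i in seq_len(s)) {
        new_pos[i, ] <- as.integer(stats::runif(d) < 0.5)
        new_vel[i, ] <- stats::runif(d, -config$v_max, config$v_max)
      }
      swarm$position <- cbind(swarm$position, new_pos)
      swarm$velocity <- cbind(swarm$velocity, new_vel)
      swarm$pbest <- cbind(swarm$pbest, matrix(0L, s, d))
      swarm$gbest <- c(swarm$gbest, rep(0L, d))
      active_pool <- c(active_pool, new_idx)
      swarm$stagnation <- 0L
      iter_in_phase <- 0L
      phase <- phase + 1L
      next
    }

    # move the swarm: per particle, scalar r1/r2 then per-dimension transfer
    for (i in seq_len(s)) {
      swarm$velocity[i, ] <- update_velocity(
        swarm$velocity[i, ], swarm$position[i, ], swarm$pbest[i, ],
        swarm$gbest, config)
      swarm$position[i, ] <- update_position(swarm$velocity[i, ])
    }
  }

  final_acc <- evaluator(best$subset)
  sel <- best$subset[order(rank_pos[best$subset])]  # report in ranked order
  group_of <- rep(seq_len(groups$k), lengths(groups$groups))
  structure(list(
    selected = sel,
    acc = final_acc,
    fs = length(sel),
    feature_ids = groups$feature_ids[rank_pos[sel]],
    ig_values = groups$ig[rank_pos[sel]],
    group_index = group_of[rank_pos[sel]],
    history = do.call(rbind, history),
    phases = phases,
    config_snapshot = unclass(config),
    seed = config$seed
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d features selected, CV accuracy %.4f\n",
              x$fs, x$acc))
  cat(sprintf("phases searched: %d; seed %d\n",
              length(x$phases), x$seed))
  invisible(x)
}

#' Per-iteration trajectory of a selection run
#'
#' @param result A `selection_result`.
#' @return Data frame `phase, iteration, gbest_in_fitness, active_pool_size,
#'   gbest_subset_size`.
#' @export
trajectory <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  result$history
}
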