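# Partition IG-ranked features into contiguous groups of approximately equal
# total information gain. Group 1 holds the highest-IG features, so in a
# typical expression dataset it is small and information-dense while the tail
# groups are large and noisy.

#' Number of feature groups
#'
#' `k = ceiling(n_features / gamma)` where `gamma` is the target number of
#' features per group. `gamma` larger than the feature count yields a single
#' group with a warning.
#'
#' @param n_features Total feature count (>= 1).
#' @param gamma Target features per group (>= 1, default 100).
#' @return Integer group count `k`, `1 <= k <= n_features`.
#' @export
group_count <- function(n_features, gamma = 100) {
  if (n_features < 1) stop_validation("n_features must be >= 1")
  if (gamma < 1) stop_validation("gamma must be >= 1")
  if (gamma > n_features) {
    warning("gamma (", gamma, ") exceeds n_features (", n_features,
            "); using a single group")
    return(1L)
  }
  as.integer(ceiling(n_features / gamma))
}

#' Information index: target IG mass per group
#'
#' Total absolute information gain divided by the group count; a group is
#' closed once its cumulative IG reaches this target.
#'
#' @param ig_values Non-negative IG values (bits).
#' @param k Group count (>= 1).
#' @return Information index in bits.
#' @export
information_index <- function(ig_values, k) {
  if (length(k) != 1 || is.na(k) || k < 1) stop_validation("k must be a positive integer")
  sum(abs(ig_values)) / k
}

#' Partition ranked features into k contiguous groups
#'
#' Greedy sweep over the descending-ranked features: IG accumulates into the
#' current group, which closes when its cumulative IG first reaches the
#' information index, or earlier when only enough features remain to keep all
#' later groups non-empty. Residual features always join the final group, so
#' the groups form an exact partition of the ranked order.
#'
#' @param ranked A `ranked_features` object from [rank_features()].
#' @param k Number of groups (`1 <= k <=` number of features).
#' @return An object of class `feature_groups` with elements `groups` (list of
#'   `k` integer vectors of original feature indices, ranked order preserved),
#'   `k`, `i_index`, plus the ranked `order`, `ig`, and `feature_ids` carried
#'   through for downstream reporting.
#' @export
partition_features <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_features"))
  n <- length(ranked$order)
  k <- as.integer(k)
  if (k < 1 || k > n) {
    stop_validation("k must be between 1 and the number of features (", n, ")")
  }
  i_index <- information_index(ranked$ig, k)
  groups <- vector("list", k)
  start <- 1L
  for (g in seq_len(k - 1L)) {
    cum <- 0
    end <- start
    # close when the IG target is reached, but leave >= 1 feature per later group
    max_end <- n - (k - g)
    while (end <= max_end) {
      cum <- cum + ranked$ig[end]
      if (cum >= i_index - 1e-12) break
      end <- end + 1L
    }
    end <- min(end, max_end)
    groups[[g]] <- ranked$order[start:end]
    start <- end + 1L
  }
  groups[[k]] <- ranked$order[start:n]
  structure(list(groups = groups, k = k, i_index = i_index,
                 order = ranked$order, ig = ranked$ig,
                 feature_ids = ranked$feature_ids),
            class = "feature_groups")
}

#' @export
print.feature_groups <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("feature_groups: k=%d, information index %.4f bits\n",
              x$k, x$i_index))
  cat("group sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Export a grouped ranking as a data frame
#'
#' One row per feature in ranked order: `feature_id`, `ig_value`,
#' `group_index`.
#'
#' @param groups A `feature_groups` object.
#' @return Data frame with one row per feature.
#' @export
grouping_table <- function(groups) {
  stopifnot(inherits(groups, "feature_groups"))
  gi <- rep(seq_len(groups$k), lengths(groups$groups))
  data.frame(feature_id = groups$feature_ids,
             ig_value = groups$ig,
             group_index = gi,
             stringsAsFactors = FALSE)
}
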