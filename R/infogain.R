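# Entropy-based feature scoring. All entropies are in bits (log base 2) and
# zero-probability terms contribute exactly 0.

#' Equal-width discretization scheme
#'
#' Continuous expression values are discretized per feature into `n_bins`
#' equal-width bins between the observed minimum and maximum before any
#' entropy is estimated. A constant feature maps all samples to a single bin.
#'
#' @param n_bins Number of bins (>= 2, default 10).
#' @return An object of class `discretization_scheme`.
#' @export
discretization_scheme <- function(n_bins = 10) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2) stop_validation("n_bins must be >= 2")
  structure(list(method = "equal_width", n_bins = n_bins),
            class = "discretization_scheme")
}

#' Discretize a numeric vector under a scheme
#'
#' @param x Numeric vector (finite values).
#' @param scheme A [discretization_scheme()].
#' @return Integer bin codes in `1..n_bins` (all `1` for a constant vector).
#' @export
discretize <- function(x, scheme = discretization_scheme()) {
  if (any(!is.finite(x))) stop_validation("feature values must be finite")
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  # n_bins - 1 interior cut points, strictly increasing
  edges <- seq(r[1], r[2], length.out = scheme$n_bins + 1L)[-c(1L, scheme$n_bins + 1L)]
  findInterval(x, edges, left.open = TRUE) + 1L
}

#' Class entropy H(C) in bits
#'
#' `-sum_i P(C_i) log2 P(C_i)` with `P(C_i)` the empirical class frequency.
#'
#' @param labels Vector of class codes (any discrete type).
#' @return Entropy in bits.
#' @export
class_entropy <- function(labels) {
  if (length(labels) == 0) stop_validation("labels must be non-empty")
  p <- tabulate(match(labels, unique(labels)))
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Conditional class entropy H(C | bins) in bits
#'
#' Weighted average over bins of the class entropy within each bin, equal to
#' `-sum_ij P(C_i, S_j) log2 P(C_i | S_j)` over the joint contingency table.
#'
#' @param feature_bins Discrete bin codes, one per sample.
#' @param labels Class codes, same length.
#' @return Entropy in bits.
#' @export
conditional_entropy <- function(feature_bins, labels) {
  if (length(feature_bins) != length(labels)) {
    stop_validation("feature_bins and labels must have equal length")
  }
  if (length(labels) == 0) stop_validation("inputs must be non-empty")
  tab <- table(feature_bins, labels)
  n <- sum(tab)
  bin_w <- rowSums(tab) / n
  h_within <- apply(tab, 1, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log2(p))
  })
  sum(bin_w * h_within)
}

#' Joint entropy H(C, bins) in bits
#'
#' `-sum_ij P(C_i, S_j) log2 P(C_i, S_j)` over the joint cells.
#'
#' @inheritParams conditional_entropy
#' @return Entropy in bits.
#' @export
joint_entropy <- function(feature_bins, labels) {
  if (length(feature_bins) != length(labels)) {
    stop_validation("feature_bins and labels must have equal length")
  }
  if (length(labels) == 0) stop_validation("inputs must be non-empty")
  p <- as.vector(table(feature_bins, labels))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

#' Information gain of one feature, in bits
#'
#' `IG(f) = H(C) - H(C | f)` where the feature is first discretized under
#' `scheme`. The result is clipped to 0 when a tiny negative value (within
#' `-1e-12`) arises from floating-point cancellation; IG is theoretically
#' non-negative.
#'
#' @param feature_values Numeric vector of expression values.
#' @param labels Class codes, same length.
#' @param scheme A [discretization_scheme()].
#' @return Information gain in bits.
#' @export
information_gain <- function(feature_values, labels,
                             scheme = discretization_scheme()) {
  if (length(feature_values) != length(labels)) {
    stop_validation("feature_values and labels must have equal length")
  }
  bins <- discretize(feature_values, scheme)
  ig <- class_entropy(labels) - conditional_entropy(bins, labels)
  if (ig < 0) {
    if (ig < -1e-12) stop_validation("negative information gain: numerical fault")
    ig <- 0
  }
  ig
}

# Vectorized IG over all columns of a dataset; returns one value per feature.
dataset_information_gain <- function(dataset, scheme = discretization_scheme()) {
  X <- dataset$expression
  y <- dataset$labels
  hc <- class_entropy(y)
  m <- length(dataset$classes)
  nb <- scheme$n_bins
  n <- length(y)
  vapply(seq_len(ncol(X)), function(j) {
    bins <- discretize(X[, j], scheme)
    # joint counts via a single tabulate over combined codes
    counts <- tabulate((bins - 1L) * m + y, nbins = nb * m)
    cm <- matrix(counts, ncol = m, byrow = TRUE)
    bw <- rowSums(cm)
    keep <- bw > 0
    hcond <- sum(vapply(which(keep), function(b) {
      p <- cm[b, ][cm[b, ] > 0] / bw[b]
      (bw[b] / n) * (-sum(p * log2(p)))
    }, numeric(1)))
    max(hc - hcond, 0)
  }, numeric(1))
}

#' Rank all features by descending information gain
#'
#' Ties are broken by ascending original feature index, so the ranking is
#' stable and identical across platforms.
#'
#' @param dataset An [expression_dataset()].
#' @param scheme A [discretization_scheme()].
#' @return An object of class `ranked_features` with elements `order`
#'   (feature indices, best first), `ig` (IG per feature in `order`,
#'   non-increasing), `feature_ids` (ids in ranked order).
#' @export
rank_features <- function(dataset, scheme = discretization_scheme()) {
  ig <- dataset_information_gain(dataset, scheme)
  ord <- order(-ig, seq_along(ig))
  structure(list(order = ord, ig = ig[ord],
                 feature_ids = dataset$feature_ids[ord]),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("ranked_features: %d features, IG range [%.4f, %.4f] bits\n",
              length(x$order), min(x$ig), max(x$ig)))
  invisible(x)
}
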