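# Synthetic high-dimensional, small-sample expression data with planted
# structure, so every selection stage is testable without external downloads.
# The generative model is a Gaussian class-shift: informative features get
# class-dependent means spaced by `effect_size` within-class standard
# deviations, redundant features are noisy copies of informative ones, and
# irrelevant features are standard normal independent of the class.

#' Specification of a synthetic expression dataset
#'
#' @param n_samples Number of samples.
#' @param n_features Total number of features.
#' @param n_informative Features with class-dependent means.
#' @param n_redundant Noisy copies of randomly chosen informative features.
#' @param n_classes Number of classes (2-4 covers the usual benchmark range,
#'   larger values are allowed).
#' @param effect_size Separation between adjacent class means, in within-class
#'   SD units (default 1.5).
#' @param redundancy_noise_sd SD of the noise added to redundant copies
#'   (default 0.3).
#' @param class_proportions Class mix summing to 1 (default balanced). Counts
#'   are apportioned by largest remainder, so they match exactly.
#' @param seed RNG seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100, n_features = 2000,
                           n_informative = 20, n_redundant = 30,
                           n_classes = 2, effect_size = 1.5,
                           redundancy_noise_sd = 0.3,
                           class_proportions = NULL, seed = 1) {
  if (n_informative + n_redundant > n_features) {
    stop_validation("n_informative + n_redundant must not exceed n_features")
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop_validation("redundant features require at least one informative feature")
  }
  if (effect_size < 0) stop_validation("effect_size must be >= 0")
  if (n_classes < 2) stop_validation("n_classes must be >= 2")
  class_proportions <- class_proportions %||% rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes ||
      abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions <= 0)) {
    stop_validation("class_proportions must be positive and sum to 1")
  }
  if (n_samples < n_classes) stop_validation("need at least one sample per class")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_classes = as.integer(n_classes),
                 effect_size = effect_size,
                 redundancy_noise_sd = redundancy_noise_sd,
                 class_proportions = class_proportions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Largest-remainder apportionment of n into shares p (sums exactly to n).
apportion <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(-(raw - counts), seq_along(p))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic expression dataset with known feature roles
#'
#' Features are laid out in blocks: informative first, then redundant, then
#' irrelevant; the returned `roles` vector records the role of every feature
#' and `redundant_source` maps each redundant feature to the informative
#' feature it copies.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an [expression_dataset()]), `roles`
#'   (character: `"informative"`, `"redundant"`, `"irrelevant"`), and
#'   `redundant_source` (integer, `NA` for non-redundant features).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$n_features
  ni <- spec$n_informative; nr <- spec$n_redundant
  with_rng(spec$seed, {
    counts <- apportion(n, spec$class_proportions)
    labels <- sample(rep.int(seq_len(spec$n_classes), counts))
    # centered class offsets, adjacent classes effect_size apart
    offsets <- (seq_len(spec$n_classes) - (spec$n_classes + 1) / 2) * spec$effect_size
    X <- matrix(stats::rnorm(n * p), n, p)
    if (ni > 0) {
      # random sign per informative feature so features are not all collinear
      signs <- sample(c(-1, 1), ni, replace = TRUE)
      for (j in seq_len(ni)) {
        X[, j] <- X[, j] + signs[j] * offsets[labels]
      }
    }
    source_of <- rep(NA_integer_, p)
    if (nr > 0) {
      src <- sample.int(ni, nr, replace = TRUE)
      source_of[ni + seq_len(nr)] <- src
      for (j in seq_len(nr)) {
        X[, ni + j] <- X[, src[j]] +
          stats::rnorm(n, sd = spec$redundancy_noise_sd)
      }
    }
    roles <- c(rep("informative", ni), rep("redundant", nr),
               rep("irrelevant", p - ni - nr))
    ids <- sprintf("%s_%d", c("inf", "red", "irr")[match(roles,
             c("informative", "redundant", "irrelevant"))],
             c(seq_len(ni), seq_len(nr), seq_len(p - ni - nr)))
    ds <- expression_dataset(X, paste0("class", labels), feature_ids = ids)
    list(dataset = ds, roles = roles, redundant_source = source_of)
  })
}

#' Shape presets matching widely used gene-expression benchmarks
#'
#' Four specs reproducing the (features, samples, classes) regime of the
#' public Prostate-GE (5966 x 102, 2 classes), TOX-171 (5748 x 171, 4),
#' GLIOMA (4434 x 50, 4) and Lung-discrete (325 x 73, 4) microarray
#' benchmarks, with default planted-structure parameters (30 informative,
#' 20 redundant, effect size 1.5).
#'
#' @param seed Base seed; preset i uses `seed + i - 1`.
#' @return Named list of four [synthetic_spec()] objects.
#' @export
benchmark_shape_presets <- function(seed = 1) {
  shapes <- list(
    prostate_like = c(5966, 102, 2),
    tox_like = c(5748, 171, 4),
    glioma_like = c(4434, 50, 4),
    lung_like = c(325, 73, 4)
  )
  out <- lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    synthetic_spec(n_samples = s[2], n_features = s[1], n_informative = 30,
                   n_redundant = 20, n_classes = s[3], effect_size = 1.5,
                   seed = seed + i - 1)
  })
  names(out) <- names(shapes)
  out
}
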