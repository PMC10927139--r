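# Cross-validated subset evaluation and the filter baselines.
#
# Accuracy is estimated by stratified k-fold cross-validation with folds fixed
# by a dedicated seed, so every candidate subset in a wrapper run is scored on
# identical folds. Features are standardized to zero mean / unit variance
# using training-fold statistics only. For subsets wider than a training
# fold, the linear SVM is fitted through a Cholesky factor of the Gram
# matrix, which caps the fit cost at n features per fold -- the property that
# keeps wrapper search affordable at 10^3-10^4 features.

#' Evaluation protocol for subset accuracy
#'
#' @param classifier `"svm"` (C-classification, linear kernel) or `"knn"`.
#' @param cv_folds Number of stratified CV folds (>= 2, default 5). Must not
#'   exceed the smallest class count.
#' @param cv_seed Seed fixing the fold assignment (default 1).
#' @param cost SVM regularization constant C (default 1).
#' @param k_neighbors Neighbor count for KNN (default 5).
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(classifier = c("svm", "knn"), cv_folds = 5,
                          cv_seed = 1, cost = 1, k_neighbors = 5) {
  classifier <- match.arg(classifier)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2) stop_validation("cv_folds must be >= 2")
  structure(list(classifier = classifier, cv_folds = cv_folds,
                 cv_seed = as.integer(cv_seed), cost = cost,
                 k_neighbors = as.integer(k_neighbors), metric = "accuracy"),
            class = "eval_protocol")
}

# Stratified fold assignment: within each class, samples are shuffled (under
# the protocol's cv_seed) and dealt round-robin to folds.
make_folds <- function(labels, protocol) {
  folds <- integer(length(labels))
  with_rng(protocol$cv_seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < protocol$cv_folds) {
        stop_validation("cv_folds (", protocol$cv_folds,
                        ") exceeds the smallest class count (", length(idx), ")")
      }
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(protocol$cv_folds), length(idx))
    }
  })
  folds
}

# Precompute per-fold standardized train/test matrices over ALL features once;
# any subset's fold data is then a column slice. Returned closure evaluates a
# subset (global feature indices) to a CV accuracy.
make_evaluator <- function(dataset, protocol, cache = TRUE) {
  y <- factor(dataset$labels)
  folds <- make_folds(dataset$labels, protocol)
  X <- dataset$expression
  prep <- lapply(seq_len(protocol$cv_folds), function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    list(tr = tr, te = te,
         Ztr = sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd, "/"),
         Zte = sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sd, "/"))
  })
  memo <- if (cache) new.env(parent = emptyenv()) else NULL
  function(subset) {
    if (length(subset) == 0) stop_validation("subset must be non-empty")
    key <- NULL
    if (!is.null(memo)) {
      key <- paste(subset, collapse = ",")
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
    }
    correct <- 0L
    # classifier internals (e.g. KNN tie-breaking) draw from an isolated stream
    with_rng(protocol$cv_seed + 1L, {
      for (p in prep) {
        Ztr <- p$Ztr[, subset, drop = FALSE]
        Zte <- p$Zte[, subset, drop = FALSE]
        pred <- if (protocol$classifier == "svm") {
          fit_predict_svm(Ztr, y[p$tr], Zte, protocol$cost)
        } else {
          class::knn(Ztr, Zte, y[p$tr], k = protocol$k_neighbors)
        }
        correct <- correct + sum(pred == y[p$te])
      }
    })
    acc <- correct / length(y)
    if (!is.null(memo)) memo[[key]] <- acc
    acc
  }
}

# Linear C-SVC. For subsets wider than the training-fold size the data are
# re-expressed through a Cholesky factor of the linear Gram matrix: a linear
# SVM depends on the data only through inner products, so training on an
# n x n factor A with A A' = Ztr Ztr' (and test rows B with B A' = Zte Ztr')
# yields identical predictions while capping the fit cost at n features.
fit_predict_svm <- function(Ztr, ytr, Zte, cost) {
  n <- nrow(Ztr)
  if (ncol(Ztr) > n) {
    K <- tcrossprod(Ztr)
    R <- chol(K + diag(1e-8 * mean(diag(K)) + 1e-12, n))
    Zte <- t(backsolve(R, t(tcrossprod(Zte, Ztr)), transpose = TRUE))
    Ztr <- t(R)
  }
  fit <- e1071::svm(Ztr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  stats::predict(fit, Zte)
}

#' Cross-validated accuracy of a feature subset
#'
#' Stratified `cv_folds`-fold cross-validation under the protocol's
#' classifier, restricted to the given features. Folds are fixed by
#' `protocol$cv_seed`; standardization uses training-fold statistics only.
#' The caller's RNG stream is left untouched.
#'
#' @param dataset An [expression_dataset()].
#' @param subset Integer vector of feature indices (non-empty).
#' @param protocol An [eval_protocol()].
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_subset <- function(dataset, subset, protocol = eval_protocol()) {
  if (length(subset) == 0) stop_validation("subset must be non-empty")
  if (any(subset < 1 | subset > ncol(dataset$expression))) {
    stop_validation("subset contains invalid feature indices")
  }
  make_evaluator(dataset, protocol, cache = FALSE)(as.integer(subset))
}

#' Per-feature relevance scores for the filter baselines
#'
#' `ig`: information gain on discretized values. `chi2`: Pearson chi-square
#' statistic of the binned-feature x class contingency table. `pearson`:
#' absolute Pearson correlation with the class labels; for more than two
#' classes, the maximum |r| over one-vs-rest binary encodings. A
#' zero-variance feature scores 0 under all three methods.
#'
#' @param dataset An [expression_dataset()].
#' @param method `"ig"`, `"chi2"`, or `"pearson"`.
#' @param scheme A [discretization_scheme()] (used by `ig` and `chi2`).
#' @return Numeric vector of non-negative scores, one per feature.
#' @export
feature_scores <- function(dataset, method = c("ig", "chi2", "pearson"),
                           scheme = discretization_scheme()) {
  method <- match.arg(method)
  X <- dataset$expression
  y <- dataset$labels
  switch(method,
    ig = dataset_information_gain(dataset, scheme),
    chi2 = vapply(seq_len(ncol(X)), function(j) {
      chi2_statistic(discretize(X[, j], scheme), y)
    }, numeric(1)),
    pearson = {
      classes <- sort(unique(y))
      vapply(seq_len(ncol(X)), function(j) {
        x <- X[, j]
        if (stats::sd(x) == 0) return(0)
        if (length(classes) == 2) {
          abs(stats::cor(x, as.numeric(y == classes[2])))
        } else {
          max(vapply(classes, function(cl) {
            abs(stats::cor(x, as.numeric(y == cl)))
          }, numeric(1)))
        }
      }, numeric(1))
    })
}

# Pearson chi-square statistic sum (O-E)^2 / E of a bins x classes table.
# Degenerate tables (a single occupied bin) carry no association: statistic 0.
chi2_statistic <- function(bins, labels) {
  tab <- table(bins, labels)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Filter-based feature selection at the standard threshold
#'
#' Informative features are those with a strictly positive score; the top
#' `ceiling(n_informative / 2)` by score are returned (score ties broken by
#' ascending feature index).
#'
#' @inheritParams feature_scores
#' @return Integer vector of selected feature indices.
#' @export
filter_select <- function(dataset, method = c("ig", "chi2", "pearson"),
                          scheme = discretization_scheme()) {
  scores <- feature_scores(dataset, method, scheme)
  informative <- which(scores > 0)
  if (length(informative) == 0) {
    stop_validation("no informative features (all scores are zero)")
  }
  n_sel <- ceiling(length(informative) / 2)
  ord <- order(-scores, seq_along(scores))
  sort(ord[seq_len(n_sel)])
}

#' Plain binary particle swarm wrapper over all features
#'
#' The grouped search with a single group holding every feature: the swarm
#' maximizes cross-validated accuracy over the full feature space with the
#' same update rules as [run_gpso()].
#'
#' @param dataset An [expression_dataset()].
#' @param config A [gpso_config()].
#' @param protocol An [eval_protocol()].
#' @return A `selection_result` (see [run_gpso()]).
#' @export
pso_select <- function(dataset, config = gpso_config(), protocol = eval_protocol()) {
  p <- ncol(dataset$expression)
  ranked <- structure(list(order = seq_len(p), ig = rep(0, p),
                           feature_ids = dataset$feature_ids),
                      class = "ranked_features")
  groups <- partition_features(ranked, 1L)
  run_gpso(groups, dataset, config, protocol)
}

#' Hybrid filter + particle swarm selection
#'
#' Runs [filter_select()] and then the plain PSO wrapper restricted to the
#' surviving features (the IG-PSO / Chis-PSO / Pearson-PSO compositions).
#' Selected indices refer to the original dataset.
#'
#' @inheritParams filter_select
#' @param config A [gpso_config()].
#' @param protocol An [eval_protocol()].
#' @return A `selection_result`; `selected` is always a subset of the filter's
#'   survivors.
#' @export
hybrid_select <- function(dataset, filter_method = c("ig", "chi2", "pearson"),
                          scheme = discretization_scheme(),
                          config = gpso_config(), protocol = eval_protocol()) {
  survivors <- filter_select(dataset, filter_method, scheme)
  sub <- expression_dataset(dataset$expression[, survivors, drop = FALSE],
                            dataset$classes[dataset$labels],
                            feature_ids = dataset$feature_ids[survivors],
                            sample_ids = dataset$sample_ids)
  res <- pso_select(sub, config, protocol)
  res$selected <- survivors[res$selected]
  res$filter_survivors <- survivors
  res
}

#' Benchmark selectors over datasets and protocols
#'
#' Applies each selector to each dataset under each protocol and reports two
#' tables in the layout of published comparisons: accuracy (percent) and
#' feature scale (subset size), one row per dataset/protocol combination plus
#' a trailing `Average` row. Selector failures are recorded as `NA` with a
#' warning and excluded from averages.
#'
#' @param datasets Named list of [expression_dataset()] objects.
#' @param algorithms Named list of selector functions; each is called as
#'   `fn(dataset, protocol)` and must return either an integer index vector or
#'   a `selection_result`.
#' @param protocols Named list of [eval_protocol()] objects (default a single
#'   SVM protocol).
#' @return List with `acc` and `fs` [rank_table()] objects (plus `acc_df`,
#'   `fs_df` data frames including the `Average` row).
#' @export
benchmark <- function(datasets, algorithms,
                      protocols = list(svm = eval_protocol("svm"))) {
  stopifnot(length(datasets) >= 1, length(algorithms) >= 1)
  rows <- list(); acc_mat <- NULL
  combo <- expand.grid(ds = names(datasets), pr = names(protocols),
                       stringsAsFactors = FALSE)
  acc_mat <- matrix(NA_real_, nrow(combo), length(algorithms),
                    dimnames = list(NULL, names(algorithms)))
  fs_mat <- acc_mat
  row_labels <- character(nrow(combo))
  for (i in seq_len(nrow(combo))) {
    ds <- datasets[[combo$ds[i]]]
    pr <- protocols[[combo$pr[i]]]
    row_labels[i] <- if (length(protocols) > 1) {
      paste(combo$pr[i], combo$ds[i], sep = ":")
    } else combo$ds[i]
    for (a in names(algorithms)) {
      sel <- tryCatch(algorithms[[a]](ds, pr), error = function(e) {
        warning("selector '", a, "' failed on '", combo$ds[i], "': ",
                conditionMessage(e))
        NULL
      })
      if (is.null(sel)) next
      idx <- if (inherits(sel, "selection_result")) sel$selected else as.integer(sel)
      acc_mat[i, a] <- 100 * evaluate_subset(ds, idx, pr)
      fs_mat[i, a] <- length(idx)
    }
  }
  acc_df <- rbind(as.data.frame(acc_mat),
                  colMeans(acc_mat, na.rm = TRUE))
  fs_df <- rbind(as.data.frame(fs_mat), colMeans(fs_mat, na.rm = TRUE))
  rownames(acc_df) <- rownames(fs_df) <- c(row_labels, "Average")
  list(
    acc = rank_table(acc_mat, rep("higher_better", nrow(acc_mat)),
                     row_labels = row_labels, column_labels = names(algorithms)),
    fs = rank_table(fs_mat, rep("lower_better", nrow(fs_mat)),
                    row_labels = row_labels, column_labels = names(algorithms)),
    acc_df = acc_df, fs_df = fs_df
  )
}
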