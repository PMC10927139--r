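# Friedman omnibus comparison of k algorithms over N datasets, with the
# F-distributed refinement of the chi-square statistic and an upper-alpha
# F critical value for the decision.

#' Algorithm x dataset score table
#'
#' @param values Numeric matrix, N dataset rows x k algorithm columns.
#' @param row_direction Character vector, per row `"higher_better"` (e.g.
#'   accuracy) or `"lower_better"` (e.g. subset size).
#' @param row_labels,column_labels Optional labels.
#' @param allow_na Permit missing cells (e.g. failed benchmark entries);
#'   default `FALSE`. Tables with missing cells cannot be ranked.
#' @return An object of class `rank_table`.
#' @export
rank_table <- function(values, row_direction, row_labels = NULL,
                       column_labels = NULL, allow_na = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop_validation("score table needs >= 1 row and >= 2 columns")
  }
  if (!allow_na && any(!is.finite(values))) {
    stop_validation("score table contains non-finite values")
  }
  row_direction <- match.arg(row_direction,
                             c("higher_better", "lower_better"),
                             several.ok = TRUE)
  if (length(row_direction) == 1) {
    row_direction <- rep(row_direction, nrow(values))
  }
  if (length(row_direction) != nrow(values)) {
    stop_validation("row_direction must have one entry per row")
  }
  structure(list(values = values, row_direction = row_direction,
                 row_labels = row_labels %||% paste0("row", seq_len(nrow(values))),
                 column_labels = column_labels %||% colnames(values) %||%
                   paste0("alg", seq_len(ncol(values)))),
            class = "rank_table")
}

#' Within-row average ranks
#'
#' The best value in each row gets rank 1 (the largest value when the row is
#' `higher_better`, the smallest when `lower_better`); ties receive the
#' average of the ranks they span.
#'
#' @param table A [rank_table()].
#' @return N x k matrix of ranks; each row sums to `k(k+1)/2`.
#' @export
rank_rows <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  if (any(!is.finite(table$values))) {
    stop_validation("cannot rank rows containing non-finite values")
  }
  ranks <- t(vapply(seq_len(nrow(table$values)), function(i) {
    v <- table$values[i, ]
    if (table$row_direction[i] == "higher_better") rank(-v) else rank(v)
  }, numeric(ncol(table$values))))
  dimnames(ranks) <- list(table$row_labels, table$column_labels)
  ranks
}

#' Friedman chi-square statistic
#'
#' `(12 N / (k (k+1))) * (sum_j R_j^2 - k (k+1)^2 / 4)` with `R_j` the mean
#' rank of algorithm j over the N rows. The classical statistic without tie
#' correction; `tie_correction = TRUE` divides by the standard tie factor
#' `1 - sum(t^3 - t) / (N k (k^2 - 1))`.
#'
#' @param ranks N x k matrix of within-row ranks (rows sum to `k(k+1)/2`).
#' @param tie_correction Apply the tie correction factor (default `FALSE`).
#' @return The chi-square statistic, in `[0, N(k-1)]` when uncorrected.
#' @export
friedman_chi2 <- function(ranks, tie_correction = FALSE) {
  N <- nrow(ranks); k <- ncol(ranks)
  if (any(abs(rowSums(ranks) - k * (k + 1) / 2) > 1e-8)) {
    stop_validation("each rank row must sum to k(k+1)/2")
  }
  Rj <- colMeans(ranks)
  chi2 <- 12 * N / (k * (k + 1)) * (sum(Rj^2) - k * (k + 1)^2 / 4)
  if (tie_correction) {
    tie_sum <- sum(apply(ranks, 1, function(r) {
      t <- table(r); sum(t^3 - t)
    }))
    denom <- 1 - tie_sum / (N * k * (k^2 - 1))
    if (denom <= 0) stop_validation("degenerate tie structure (all values tied)")
    chi2 <- chi2 / denom
  }
  chi2
}

#' F-form of the Friedman statistic
#'
#' `F = (N-1) chi2 / (N (k-1) - chi2)`, F-distributed with `k-1` and
#' `(N-1)(k-1)` degrees of freedom under the null.
#'
#' @param chi2 Friedman chi-square statistic (must be `< N(k-1)`).
#' @param N Number of dataset rows.
#' @param k Number of algorithms.
#' @return The F statistic.
#' @export
friedman_f <- function(chi2, N, k) {
  denom <- N * (k - 1) - chi2
  if (denom <= 0) {
    stop_validation("degenerate statistic: chi2 >= N(k-1), F is undefined ",
                    "(all rows rank the algorithms identically)")
  }
  (N - 1) * chi2 / denom
}

#' Upper-alpha F critical value
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return The upper-`alpha` quantile of the F(df1, df2) distribution.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  if (df1 < 1 || df2 < 1) stop_validation("degrees of freedom must be >= 1")
  stats::qf(1 - alpha, df1, df2)
}

#' Friedman test over a score table
#'
#' Ranks each row ([rank_rows()]), computes the chi-square statistic
#' ([friedman_chi2()]) and its F-form ([friedman_f()]), and compares against
#' the upper-`alpha` F critical value with `k-1` and `(N-1)(k-1)` degrees of
#' freedom.
#'
#' @param table A [rank_table()].
#' @param alpha Significance level (default 0.05).
#' @param tie_correction Passed to [friedman_chi2()] (default `FALSE`).
#' @return An object of class `friedman_result`: `ranks`, `mean_ranks`,
#'   `chi2`, `f_stat`, `df1`, `df2`, `alpha`, `critical_value`, `reject`.
#' @export
friedman_test <- function(table, alpha = 0.05, tie_correction = FALSE) {
  ranks <- rank_rows(table)
  N <- nrow(ranks); k <- ncol(ranks)
  chi2 <- friedman_chi2(ranks, tie_correction)
  f_stat <- friedman_f(chi2, N, k)
  df1 <- k - 1; df2 <- (N - 1) * (k - 1)
  crit <- f_critical(alpha, df1, df2)
  structure(list(ranks = ranks, mean_ranks = colMeans(ranks), chi2 = chi2,
                 f_stat = f_stat, df1 = df1, df2 = df2, alpha = alpha,
                 critical_value = crit, reject = f_stat > crit,
                 N = N, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat("Friedman test:", x$N, "datasets x", x$k, "algorithms\n")
  cat(sprintf("  chi-square = %.4f   F = %.4f   df = (%d, %d)\n",
              x$chi2, x$f_stat, x$df1, x$df2))
  cat(sprintf("  critical value F(%d, %d) at alpha = %g: %.4f\n",
              x$df1, x$df2, x$alpha, x$critical_value))
  cat("  decision:", if (x$reject) {
    "reject the null (algorithms differ significantly)"
  } else "fail to reject the null", "\n")
  mr <- sort(x$mean_ranks)
  cat("  mean ranks (best first):\n")
  for (nm in names(mr)) cat(sprintf("    %-14s %.3f\n", nm, mr[[nm]]))
  invisible(x)
}
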