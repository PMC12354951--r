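#' Correlation and error metrics
#'
#' Spearman rank correlation (average ranks for ties), Pearson
#' product-moment correlation, and mean squared error, with explicit
#' contract checks: correlations require length >= 2 and non-constant
#' vectors (a constant vector makes the correlation undefined and raises a
#' `gg_metric_undefined` error).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single number.
#' @export
spearman <- function(x, y) {
  check_metric_args(x, y, min_n = 2L)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    gg_stop("gg_metric_undefined",
            "spearman undefined: a vector has zero rank variance")
  }
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman
#' @export
pearson <- function(x, y) {
  check_metric_args(x, y, min_n = 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    gg_stop("gg_metric_undefined", "pearson undefined: a vector is constant")
  }
  stats::cor(x, y, method = "pearson")
}

#' @rdname spearman
#' @export
mse <- function(x, y) {
  check_metric_args(x, y, min_n = 1L)
  mean((x - y)^2)
}

#' @noRd
check_metric_args <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y)) {
    gg_stop("gg_contract_error", "metric inputs must be numeric vectors")
  }
  if (length(x) != length(y)) {
    gg_stop("gg_contract_error", "vectors of unequal length: %d vs %d",
            length(x), length(y))
  }
  if (length(x) < min_n) {
    gg_stop("gg_contract_error", "need at least %d observations, got %d",
            min_n, length(x))
  }
  if (anyNA(x) || anyNA(y)) gg_stop("gg_contract_error", "NA in metric input")
}

#' Metric report for predictions against labels
#'
#' @param preds,labels Numeric vectors.
#' @return A `metric_report`: list with `spearman`, `pearson`, `mse`, `n`.
#' @export
metric_report <- function(preds, labels) {
  structure(list(spearman = spearman(preds, labels),
                 pearson = pearson(preds, labels),
                 mse = mse(preds, labels),
                 n = length(preds)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  Spearman=%.4f  Pearson=%.4f  MSE=%.3f\n",
              x$n, x$spearman, x$pearson, x$mse))
  invisible(x)
}

#' Seeded balanced k-fold assignment
#'
#' Shuffles indices with the given seed and deals them into k folds whose
#' sizes differ by at most one.
#'
#' @param n Number of records.
#' @param k Number of folds (2 <= k <= n).
#' @param seed RNG seed.
#' @return A `split_plan`: list with `assignment` (fold id per index),
#'   `k`, `seed`.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (!is_count(n)) gg_stop("gg_config_error", "n must be a positive integer")
  if (!is_count(k, min = 2L) || k > n) {
    gg_stop("gg_config_error", "k must satisfy 2 <= k <= n (n=%d, k=%s)", n, format(k))
  }
  perm <- with_seed(seed, sample.int(n))
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), length.out = n)
  structure(list(assignment = assignment, k = as.integer(k), seed = as.integer(seed)),
            class = "split_plan")
}

#' Seeded holdout split by fraction
#'
#' @param n Number of records.
#' @param fraction Test fraction in (0, 1); the test set gets
#'   `round(fraction * n)` records.
#' @param seed RNG seed.
#' @return List with `train_idx`, `test_idx`, `fraction`, `seed`.
#' @export
holdout_split <- function(n, fraction, seed = 1L) {
  if (!is_count(n, min = 2L)) gg_stop("gg_config_error", "n must be >= 2")
  if (fraction <= 0 || fraction >= 1) {
    gg_stop("gg_config_error", "fraction must be in (0, 1)")
  }
  n_test <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  perm <- with_seed(seed, sample.int(n))
  list(train_idx = sort(perm[(n_test + 1L):n]), test_idx = sort(perm[seq_len(n_test)]),
       fraction = fraction, seed = as.integer(seed))
}

#' Global alignment identity between two sequences
#'
#' Optimal global alignment with unit match score and zero mismatch/gap
#' penalties (so the score is the longest common subsequence length),
#' divided by the length of the longer sequence.  Symmetric, in \[0, 1\].
#' This single transparent definition replaces heavier external alignment
#' tooling for redundancy filtering.
#'
#' @param a,b Non-empty sequence strings.
#' @export
similarity <- function(a, b) {
  a <- normalize_rna(a, "uniform", "sequence a")
  b <- normalize_rna(b, "uniform", "sequence b")
  x <- rna_chars(a); y <- rna_chars(b)
  n <- length(x); m <- length(y)
  prev <- numeric(m + 1L)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    match_i <- x[i] == y
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + as.numeric(match_i[j]), prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L] / max(n, m)
}

#' Filter test records by similarity to a training set
#'
#' Drops every test record whose maximum alignment identity (see
#' [similarity()]) to any training record is at or above the threshold;
#' the default 0.9 is the conventional redundancy threshold for this
#' filtering step.
#'
#' @param test,train Lists of [guide_record()]s (or character vectors of
#'   sequences).
#' @param threshold Identity threshold in (0, 1\].
#' @return A `similarity_report` data.frame with columns `id`,
#'   `max_identity`, `keep`, and attributes `redundancy_rate`,
#'   `threshold`, `kept` (the retained subset of `test`).
#' @export
filter_by_similarity <- function(test, train, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) {
    gg_stop("gg_config_error", "threshold must be in (0, 1]")
  }
  test_seqs <- as_sequences(test)
  train_seqs <- as_sequences(train)
  if (length(train_seqs) == 0L) {
    gg_stop("gg_contract_error", "training set is empty")
  }
  if (length(test_seqs) == 0L) {
    rep_df <- data.frame(id = character(0), max_identity = numeric(0), keep = logical(0))
    attr(rep_df, "redundancy_rate") <- NaN
  } else {
    max_id <- vapply(test_seqs, function(ts) {
      max(vapply(train_seqs, function(tr) similarity(ts, tr), numeric(1)))
    }, numeric(1))
    keep <- max_id < threshold
    rep_df <- data.frame(id = names(test_seqs), max_identity = unname(max_id),
                         keep = unname(keep))
    attr(rep_df, "redundancy_rate") <- mean(!keep)
    attr(rep_df, "kept") <- if (is.list(test)) test[keep] else test[keep]
  }
  attr(rep_df, "threshold") <- threshold
  class(rep_df) <- c("similarity_report", "data.frame")
  rep_df
}

#' @noRd
as_sequences <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% sprintf("seq_%d", seq_along(x))
    return(stats::setNames(x, ids))
  }
  stats::setNames(vapply(x, `[[`, character(1), "sequence"),
                  vapply(x, `[[`, character(1), "id"))
}

#' Label-permutation significance test for predictive correlation
#'
#' The observed statistic is the Spearman correlation between predictions
#' and labels; the null distribution is built by seeded label shuffles.
#' Two-sided p-value with the add-one correction:
#' `p = (1 + #{|null| >= |observed|}) / (B + 1)`.
#'
#' @param preds,labels Numeric vectors of equal length >= 3.
#' @param B Number of permutations (>= 19).
#' @param seed RNG seed.
#' @return A `permutation_result`: list with `observed`, `null`,
#'   `p_value`, `B`, `seed`.
#' @export
permutation_test <- function(preds, labels, B = 999L, seed = 1L) {
  check_metric_args(preds, labels, min_n = 3L)
  if (!is_count(B, min = 19L)) {
    gg_stop("gg_config_error", "B must be an integer >= 19, got %s", format(B))
  }
  observed <- spearman(preds, labels)  # errors on constant labels
  null_stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stats::cor(preds, sample(labels), method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (B + 1)
  structure(list(observed = observed, null = null_stats, p_value = p,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed Spearman=%.4f, B=%d, p=%.4g\n",
              x$observed, x$B, x$p_value))
  invisible(x)
}
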