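# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own implementation paths.

# Random valid dot-bracket string of length n (uniform-ish recursive
# construction; always balanced and non-crossing).
random_dot_bracket <- function(n, p_pair = 0.4) {
  if (n <= 0L) return("")
  if (n >= 2L && stats::runif(1) < p_pair) {
    inner <- sample.int(n - 1L, 1L) - 1L  # 0..n-2 inside the pair
    paste0("(", random_dot_bracket(inner, p_pair), ")",
           random_dot_bracket(n - 2L - inner, p_pair))
  } else {
    paste0(".", random_dot_bracket(n - 1L, p_pair))
  }
}

# Exhaustive enumeration of all valid non-crossing pairings; returns the
# maximum pair count.  Feasible for length <= ~12.
enum_max_pairs <- function(seq, min_loop = 3L,
                           allowed = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  chars <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < 1L) return(0L)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in (i + 1L):j) {
      if (paste0(chars[i], chars[k]) %in% allowed && (k - i - 1L) >= min_loop) {
        cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (cand > best) best <- cand
      }
    }
    best
  }
  rec(1L, length(chars))
}

# Longest-common-subsequence length by plain recursion (tiny strings).
lcs_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    if (x[i] == y[j]) return(1L + rec(i - 1L, j - 1L))
    max(rec(i - 1L, j), rec(i, j - 1L))
  }
  rec(length(x), length(y))
}

# Definitional Spearman: Pearson correlation of average ranks, computed
# from first principles (no stats::cor).
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

pearson_oracle <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# A small model configuration keeping unit tests fast.
tiny_cfg <- function(...) {
  defaults <- list(hidden_dim = 16L, attention_heads = 2L, positional_dim = 5L,
                   batch_size = 32L, max_epochs = 8L, patience = 8L,
                   dropout = 0.1, seed = 1L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Labelled synthetic graphs for model tests.
tiny_graphs <- function(n = 40L, seed = 1L, ...) {
  spec <- synthetic_spec(n, seed = seed, ...)
  build_dataset(generate_dataset(spec))
}
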