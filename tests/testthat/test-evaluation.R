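test_that("metric examples match hand-checked values", {
  expect_equal(spearman(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)  # 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(pearson(c(0, 1, 2), 2 * c(0, 1, 2) + 1), 1.0)
  expect_equal(mse(c(3, 4), c(3, 4)), 0)
  expect_equal(mse(c(0, 0), c(3, 4)), 12.5)
})

test_that("metrics enforce their contracts", {
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), class = "gg_metric_undefined")
  expect_error(pearson(c(2, 2), c(1, 3)), class = "gg_metric_undefined")
  expect_error(spearman(1:3, 1:4), class = "gg_contract_error")
  expect_error(spearman(1, 1), class = "gg_contract_error")
  expect_error(mse(numeric(0), numeric(0)), class = "gg_contract_error")
  expect_error(mse(c(1, NA), c(1, 2)), class = "gg_contract_error")
})

test_that("metrics agree with brute-force definitional computation", {
  set.seed(2024)
  for (rep in seq_len(100)) {
    n <- sample(3:12, 1L)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.01)  # some near-ties
    y <- rnorm(n)
    expect_equal(spearman(x, y), spearman_oracle(x, y), tolerance = 1e-10)
    expect_equal(pearson(x, y), pearson_oracle(x, y), tolerance = 1e-10)
    expect_equal(mse(x, y), sum((x - y)^2) / n, tolerance = 1e-10)
  }
  # exact tie handling via average ranks
  x <- c(1, 1, 2, 3); y <- c(4, 2, 2, 1)
  expect_equal(spearman(x, y), spearman_oracle(x, y), tolerance = 1e-12)
})

test_that("make_folds partitions indices into balanced seeded folds", {
  plan <- make_folds(4, 2, seed = 3)
  expect_equal(as.vector(table(plan$assignment)), c(2L, 2L))
  expect_identical(plan, make_folds(4, 2, seed = 3))

  plan2 <- make_folds(11, 3, seed = 1)
  sizes <- unname(table(plan2$assignment))
  expect_true(max(sizes) - min(sizes) <= 1L)
  expect_equal(sum(sizes), 11L)
  expect_error(make_folds(3, 5), class = "gg_config_error")
  expect_error(make_folds(10, 1), class = "gg_config_error")
})

test_that("holdout_split draws the requested fraction", {
  sp <- holdout_split(100, 0.15, seed = 2)
  expect_length(sp$test_idx, 15L)
  expect_length(sp$train_idx, 85L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  expect_identical(sp, holdout_split(100, 0.15, seed = 2))
})

test_that("similarity is alignment identity over the longer length", {
  a <- strrep("ACGU", 5)
  expect_equal(similarity(a, a), 1.0)
  expect_equal(similarity("AAAA", "CCCC"), 0.0)
  b <- paste0(substr(a, 1, 10), "A", substr(a, 12, 20))  # one substitution
  expect_equal(similarity(a, b), 0.95)
  expect_equal(similarity(a, b), similarity(b, a))
  expect_error(similarity("", "ACGU"), class = "gg_format_error")
})

test_that("similarity matches the recursive LCS oracle on tiny strings", {
  set.seed(8)
  for (rep in seq_len(40)) {
    a <- random_rna(sample(2:6, 1L))
    b <- random_rna(sample(2:6, 1L))
    expect_equal(similarity(a, b),
                 lcs_oracle(a, b) / max(nchar(a), nchar(b)),
                 tolerance = 1e-12, info = paste(a, b))
  }
})

test_that("filter_by_similarity drops redundant records and is idempotent", {
  set.seed(91)
  train <- replicate(10, random_rna(20))
  test <- c(train[1], replicate(9, random_rna(20)))
  rep1 <- filter_by_similarity(test, train, threshold = 0.9)
  expect_true(rep1$max_identity[1] >= 0.9)
  expect_false(rep1$keep[1])

  # subset case: every test record present in train
  rep_all <- filter_by_similarity(train[1:3], train)
  expect_equal(attr(rep_all, "redundancy_rate"), 1.0)

  # filtering the kept set again drops nothing
  kept <- test[rep1$keep]
  rep2 <- filter_by_similarity(kept, train)
  expect_equal(attr(rep2, "redundancy_rate"), 0.0)

  expect_error(filter_by_similarity(test, character(0)), class = "gg_contract_error")
  expect_error(filter_by_similarity(test, train, threshold = 0), class = "gg_config_error")
})

test_that("permutation test obeys its p-value formula and contracts", {
  x <- c(5, 1, 4, 2, 8, 7, 3, 9, 6, 10)
  res <- permutation_test(x, x, B = 99, seed = 4)
  expect_equal(res$observed, 1.0)
  expect_equal(res$p_value, 0.01)  # minimal attainable p = 1/(B+1)
  expect_length(res$null, 99L)
  # formula invariant
  expect_equal(res$p_value,
               (1 + sum(abs(res$null) >= abs(res$observed))) / (res$B + 1))
  # deterministic given seed
  expect_identical(res, permutation_test(x, x, B = 99, seed = 4))

  expect_error(permutation_test(x, x, B = 0), class = "gg_config_error")
  expect_error(permutation_test(c(1, 2, 3), c(5, 5, 5), B = 99),
               class = "gg_metric_undefined")
  expect_error(permutation_test(c(1, 2), c(1, 2), B = 99), class = "gg_contract_error")
})

test_that("metric_report bundles the three metrics", {
  set.seed(3)
  x <- rnorm(20); y <- x + rnorm(20)
  rep <- metric_report(x, y)
  expect_equal(rep$spearman, spearman(x, y))
  expect_equal(rep$pearson, pearson(x, y))
  expect_equal(rep$mse, mse(x, y))
  expect_equal(rep$n, 20L)
})
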