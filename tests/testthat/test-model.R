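# Model tests use tiny_cfg()/tiny_graphs() from helper-oracles.R to stay
# fast; the heavier end-to-end learning checks live in test-acceptance.R.

test_that("model_config validates its fields", {
  expect_s3_class(model_config(), "model_config")
  expect_error(model_config(hidden_dim = 0), class = "gg_config_error")
  expect_error(model_config(dropout = 1), class = "gg_config_error")
  expect_error(model_config(hidden_dim = 10, attention_heads = 4),
               class = "gg_config_error")
  expect_error(model_config(learning_rate = 0), class = "gg_config_error")
})

test_that("initialization is deterministic in config seed", {
  m1 <- init_model(tiny_cfg(seed = 5), 4L)
  m2 <- init_model(tiny_cfg(seed = 5), 4L)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(tiny_cfg(seed = 6), 4L)
  expect_false(identical(m1$params, m3$params))
  expect_error(init_model(tiny_cfg(), 0), class = "gg_config_error")
})

test_that("forward pass is pure in eval mode and handles one node", {
  g <- tiny_graphs(3, seed = 2)[[1]]
  m <- init_model(tiny_cfg(), 4L)
  f1 <- model_forward(m, g)
  f2 <- model_forward(m, g)
  expect_identical(f1$prediction, f2$prediction)
  expect_true(is.finite(f1$prediction))

  single <- build_graph(guide_record("one", "A"))
  fs <- model_forward(m, single, return_attention = TRUE)
  expect_true(is.finite(fs$prediction))
  # lone node: attention degenerates to the self-loop with weight 1
  expect_equal(fs$attention[[1]][[1]]$weight, 1)

  wrong <- g; wrong$node_features <- cbind(g$node_features, 0)
  expect_error(model_forward(m, wrong), class = "gg_contract_error")
})

test_that("incoming attention per node and head sums to 1", {
  m <- init_model(tiny_cfg(attention_layers = 2L), 4L)
  for (g in tiny_graphs(4, seed = 9)) {
    fw <- model_forward(m, g, return_attention = TRUE)
    for (layer in fw$attention) {
      for (head in layer) {
        sums <- as.vector(tapply(head$weight, head$dst, sum))
        expect_equal(sums, rep(1, g$meta$n_nodes), tolerance = 1e-6)
      }
    }
  }
})

test_that("prediction is equivariant under node relabeling", {
  set.seed(12)
  g <- tiny_graphs(1, seed = 12)[[1]]
  m <- init_model(tiny_cfg(), 4L)
  perm <- sample(g$meta$n_nodes)           # new position of old node i
  inv <- order(perm)
  g2 <- g
  g2$node_features <- g$node_features[inv, ]
  g2$positions <- g$positions[inv]
  g2$arcs$src <- match(g$arcs$src + 1L, inv) - 1L
  g2$arcs$dst <- match(g$arcs$dst + 1L, inv) - 1L
  expect_equal(model_forward(m, g2)$prediction, model_forward(m, g)$prediction,
               tolerance = 1e-5)
})

test_that("training fits a constant-label dataset and is seed-reproducible", {
  graphs <- tiny_graphs(60, seed = 4)
  for (i in seq_along(graphs)) graphs[[i]]$label <- 55
  m <- init_model(tiny_cfg(max_epochs = 3L), 4L)
  fit <- train_model(m, graphs[1:40], graphs[41:60])
  expect_lt(min(fit$history$val_mse), 1e-2)
  expect_equal(unname(predict(fit, graphs[41:43])), rep(55, 3), tolerance = 0.05)

  # same seed -> identical loss history; history invariants hold
  graphs2 <- tiny_graphs(60, seed = 4)
  fit2 <- train_model(init_model(tiny_cfg(max_epochs = 4L), 4L),
                      graphs2[1:40], graphs2[41:60])
  fit3 <- train_model(init_model(tiny_cfg(max_epochs = 4L), 4L),
                      graphs2[1:40], graphs2[41:60])
  expect_identical(fit2$history, fit3$history)
  expect_identical(predict(fit2, graphs2[41:60]), predict(fit3, graphs2[41:60]))
  expect_length(fit2$history$train_mse, length(fit2$history$val_mse))
  expect_equal(fit2$history$val_mse[fit2$history$best_epoch],
               min(fit2$history$val_mse))
})

test_that("training contracts: labels, empty splits, shared ids", {
  graphs <- tiny_graphs(10, seed = 3)
  m <- init_model(tiny_cfg(), 4L)
  unlab <- graphs
  unlab[[2]]$label <- NA_real_
  expect_error(train_model(m, unlab[1:5], unlab[6:10]), class = "gg_contract_error")
  expect_error(train_model(m, graphs[1:5], list()), class = "gg_contract_error")
  expect_error(train_model(m, graphs[1:5], graphs[5:8]), class = "gg_contract_error")
})

test_that("predict preserves order, names and emptiness", {
  graphs <- tiny_graphs(8, seed = 6)
  m <- init_model(tiny_cfg(), 4L)
  expect_identical(predict(m, list()), numeric(0))
  p <- predict(m, graphs)
  expect_identical(names(p), vapply(graphs, function(g) g$meta$id, character(1)))
  expect_identical(p, predict(m, graphs))
  expect_length(predict(m, graphs[3]), 1L)
  bad <- graphs
  bad[[5]]$node_features <- bad[[5]]$node_features[, 1:3]
  expect_error(predict(m, bad), class = "gg_contract_error", regexp = "5")
})

test_that("fine_tune: zero epochs is the identity, training data stay fit", {
  graphs <- tiny_graphs(50, seed = 8)
  m <- train_model(init_model(tiny_cfg(max_epochs = 6L), 4L),
                   graphs[1:35], graphs[36:50])
  expect_identical(fine_tune(m, graphs[1:35], epochs = 0), m)
  expect_error(fine_tune(m, list(), epochs = 2), class = "gg_contract_error")

  val_before <- mse(unname(predict(m, graphs[36:50])),
                    vapply(graphs[36:50], `[[`, numeric(1), "label"))
  ft <- fine_tune(m, graphs[1:35], epochs = 3)
  val_after <- mse(unname(predict(ft, graphs[36:50])),
                   vapply(graphs[36:50], `[[`, numeric(1), "label"))
  expect_lt(val_after, val_before * 1.10)
})

test_that("random_search samples the space reproducibly", {
  graphs <- tiny_graphs(30, seed = 10)
  tr <- graphs[1:20]; va <- graphs[21:30]
  space1 <- list(hidden_dim = 8L, max_epochs = 2L)  # one-point space
  res1 <- random_search(space1, trials = 1L, tr, va, feature_dim = 4L, seed = 2)
  expect_equal(res1$best_config$hidden_dim, 8L)
  expect_equal(nrow(res1$trials), 1L)

  space <- list(hidden_dim = c(8L, 16L), learning_rate = c(1e-2, 1e-3),
                max_epochs = 2L)
  res2 <- random_search(space, trials = 3L, tr, va, feature_dim = 4L, seed = 5)
  res3 <- random_search(space, trials = 3L, tr, va, feature_dim = 4L, seed = 5)
  expect_identical(res2$trials, res3$trials)
  expect_equal(res2$best_val_mse, min(res2$trials$val_mse))

  expect_error(random_search(list(), 2L, tr, va, 4L), class = "gg_config_error")
  expect_error(random_search(list(nonsense = 1), 2L, tr, va, 4L),
               class = "gg_config_error")
})

test_that("checkpoints round-trip bit-identically with an auditable sidecar", {
  graphs <- tiny_graphs(12, seed = 14)
  m <- train_model(init_model(tiny_cfg(max_epochs = 2L), 4L),
                   graphs[1:8], graphs[9:12])
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(predict(back, graphs[1:10]), predict(m, graphs[1:10]))

  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(sidecar$feature_dim, 4L)
  expect_equal(sidecar$config$hidden_dim, m$config$hidden_dim)
  expect_equal(sidecar$n_params, length(unlist(m$params)))

  # corruption is detected
  writeLines("not a checkpoint", path)
  expect_error(load_checkpoint(path), class = "gg_integrity_error")
  expect_error(load_checkpoint(tempfile()), class = "gg_integrity_error")

  # sidecar/feature_dim mismatch is an integrity error
  path2 <- tempfile(fileext = ".rds")
  save_checkpoint(m, path2)
  sc <- jsonlite::read_json(paste0(path2, ".json"), simplifyVector = TRUE)
  sc$feature_dim <- 640L
  jsonlite::write_json(sc, paste0(path2, ".json"), auto_unbox = TRUE)
  expect_error(load_checkpoint(path2), class = "gg_integrity_error")
})

test_that("pooling variants and deeper stacks stay finite and trainable", {
  graphs <- tiny_graphs(20, seed = 18)
  for (pool in c("mean", "sum", "max")) {
    cfg <- tiny_cfg(pooling = pool, max_epochs = 2L, conv_layers = 2L,
                    node_mlp_layers = 1L, head_layers = 1L)
    fit <- train_model(init_model(cfg, 4L), graphs[1:14], graphs[15:20])
    expect_true(all(is.finite(predict(fit, graphs))))
  }
})
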