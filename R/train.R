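# Training, prediction, fine-tuning, hyperparameter search and
# checkpointing for gg_model objects.  Optimization is Adam over the
# flattened parameter tree; all stochastic steps (shuffling, dropout)
# draw from one seeded stream so runs are bit-reproducible.

#' @noRd
adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

#' @noRd
adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' @noRd
check_labelled <- function(graphs, what) {
  if (length(graphs) == 0L) gg_stop("gg_contract_error", "%s set is empty", what)
  lab <- vapply(graphs, `[[`, numeric(1), "label")
  if (anyNA(lab) || any(!is.finite(lab))) {
    bad <- which(is.na(lab) | !is.finite(lab))[1L]
    gg_stop("gg_contract_error", "%s graph %d ('%s') has no efficiency label",
            what, bad, graphs[[bad]]$meta$id)
  }
  lab
}

#' @noRd
eval_predictions <- function(model, graphs, chunk = 512L) {
  if (length(graphs) == 0L) return(numeric(0))
  out <- numeric(length(graphs))
  idx <- split(seq_along(graphs), ceiling(seq_along(graphs) / chunk))
  for (ii in idx) {
    batch <- make_batch(graphs[ii], model$feature_dim)
    out[ii] <- nn_forward(model, batch)$pred
  }
  out
}

#' @noRd
train_loop <- function(model, train_graphs, val_graphs, lr, max_epochs, patience,
                       batch_size, seed, init_head_bias, verbose = FALSE) {
  y_train <- check_labelled(train_graphs, "training")
  y_val <- check_labelled(val_graphs, "validation")
  cfg <- model$config
  if (init_head_bias) {
    # start the regression head at the train-label mean so the raw 0-100
    # percent scale does not have to be climbed by tiny Adam steps
    last <- length(model$params$head)
    model$params$head[[last]]$b <- mean(y_train)
  }
  skeleton <- model$params
  theta <- unlist(skeleton, use.names = FALSE)
  state <- adam_new(length(theta))
  n <- length(train_graphs)
  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  train_hist <- numeric(0)
  val_hist <- numeric(0)
  with_seed(seed, {
    bad_epochs <- 0L
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / batch_size))
      sse <- 0
      for (bi in batches) {
        batch <- make_batch(train_graphs[bi], model$feature_dim)
        fw <- nn_forward(model, batch, training = TRUE, keep_cache = TRUE)
        resid <- fw$pred - batch$labels
        sse <- sse + sum(resid^2)
        dpred <- 2 * resid / length(bi)
        grads <- nn_backward(model, batch, fw$cache, dpred)
        up <- adam_step(theta, unlist(grads, use.names = FALSE), state, lr)
        theta <- up$theta
        state <- up$state
        model$params <- utils::relist(theta, skeleton)
      }
      train_mse <- sse / n
      val_mse <- mse(eval_predictions(model, val_graphs), y_val)
      train_hist <- c(train_hist, train_mse)
      val_hist <- c(val_hist, val_mse)
      if (verbose) {
        message(sprintf("epoch %3d  train MSE %10.3f  val MSE %10.3f", epoch,
                        train_mse, val_mse))
      }
      if (val_mse < best_val) {
        best_val <- val_mse
        best_theta <- theta
        best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > patience) break
      }
    }
  })
  model$params <- utils::relist(best_theta, skeleton)
  model$history <- list(
    train_mse = train_hist, val_mse = val_hist, best_epoch = best_epoch
  )
  model
}

#' Train a guide-graph regression model
#'
#' Minimizes mean squared error on the 0-100 percent efficiency scale with
#' Adam, seeded minibatch shuffling and dropout, and early stopping on the
#' validation MSE: training halts after `patience` non-improving epochs
#' and the parameters from the best epoch are returned.  The regression
#' head's output bias is initialized to the training-label mean.
#'
#' @param model A `gg_model` from [init_model()].
#' @param train_graphs,val_graphs Disjoint lists of labelled
#'   `guide_graph`s.
#' @param cfg Optional [model_config()] overriding the model's own
#'   training settings (learning rate, batch size, epochs, patience,
#'   seed).
#' @param verbose Log per-epoch losses.
#' @return The trained `gg_model`, with `history` holding per-epoch train
#'   and validation MSE and the best epoch index.
#' @export
train_model <- function(model, train_graphs, val_graphs, cfg = model$config,
                        verbose = FALSE) {
  if (!inherits(model, "gg_model")) gg_stop("gg_contract_error", "model must be a gg_model")
  ids_train <- vapply(train_graphs, function(g) g$meta$id, character(1))
  ids_val <- vapply(val_graphs, function(g) g$meta$id, character(1))
  shared <- intersect(ids_train, ids_val)
  if (length(shared) > 0) {
    gg_stop("gg_contract_error", "train and validation sets share record id(s): %s",
            paste(utils::head(shared, 3L), collapse = ", "))
  }
  train_loop(model, train_graphs, val_graphs,
             lr = cfg$learning_rate, max_epochs = cfg$max_epochs,
             patience = cfg$patience, batch_size = cfg$batch_size,
             seed = cfg$seed, init_head_bias = TRUE, verbose = verbose)
}

#' Predict editing efficiencies for guide graphs
#'
#' Deterministic (evaluation-mode) forward pass; order-preserving.
#'
#' @param object A trained `gg_model`.
#' @param graphs List of `guide_graph`s with the model's feature
#'   dimension.
#' @param ... Unused.
#' @return Named numeric vector of predicted efficiencies.
#' @export
predict.gg_model <- function(object, graphs, ...) {
  if (length(graphs) == 0L) return(numeric(0))
  preds <- eval_predictions(object, graphs)
  names(preds) <- vapply(graphs, function(g) g$meta$id, character(1))
  preds
}

#' Single-graph forward pass, optionally with attention weights
#'
#' @param model A `gg_model`.
#' @param g A `guide_graph`.
#' @param return_attention When `TRUE`, also return per-layer per-head
#'   attention weights: for each attention layer a list of data.frames
#'   (`src`, `dst`, `weight`; 0-based, including the implicit self-loop
#'   arcs).  Each node's incoming weights sum to 1.
#' @return List with `prediction` and (optionally) `attention`.
#' @export
model_forward <- function(model, g, return_attention = FALSE) {
  batch <- make_batch(list(g), model$feature_dim)
  fw <- nn_forward(model, batch, return_attention = return_attention)
  out <- list(prediction = unname(fw$pred))
  if (return_attention) {
    src0 <- batch$asrc - 1L
    dst0 <- batch$adst - 1L
    out$attention <- lapply(fw$attention, function(layer) {
      lapply(layer, function(alpha) {
        data.frame(src = src0, dst = dst0, weight = alpha)
      })
    })
  }
  out
}

#' Fine-tune a trained model on a new labelled dataset
#'
#' Continues optimization from the current parameters at a lower learning
#' rate (transfer-learning style).  `epochs = 0` returns the model
#' unchanged.  When no validation set is given the fine-tuning data
#' monitor progress and the final-epoch parameters are kept.
#'
#' @param model A trained `gg_model`.
#' @param graphs Labelled `guide_graph`s to adapt to.
#' @param epochs Number of fine-tuning epochs.
#' @param learning_rate Defaults to a tenth of the training rate.
#' @param val_graphs Optional validation graphs enabling early stopping
#'   and best-epoch selection.
#' @param seed RNG seed for shuffling/dropout.
#' @return The adapted `gg_model`.
#' @export
fine_tune <- function(model, graphs, epochs = 10L,
                      learning_rate = model$config$learning_rate * 0.1,
                      val_graphs = NULL, seed = model$config$seed + 1L) {
  if (!inherits(model, "gg_model")) gg_stop("gg_contract_error", "model must be a gg_model")
  if (!is.numeric(epochs) || epochs < 0) gg_stop("gg_config_error", "epochs must be >= 0")
  if (epochs == 0L) return(model)
  check_labelled(graphs, "fine-tuning")
  if (is.null(val_graphs)) {
    train_loop(model, graphs, graphs, lr = learning_rate, max_epochs = epochs,
               patience = epochs, batch_size = model$config$batch_size,
               seed = seed, init_head_bias = FALSE)
  } else {
    train_loop(model, graphs, val_graphs, lr = learning_rate, max_epochs = epochs,
               patience = model$config$patience, batch_size = model$config$batch_size,
               seed = seed, init_head_bias = FALSE)
  }
}

#' Seeded random hyperparameter search
#'
#' Samples configurations uniformly from a discrete space (a named list of
#' candidate values for [model_config()] fields), trains each and returns
#' the configuration minimizing validation MSE together with the full
#' trial table.  A lightweight stand-in for large managed
#' hyperparameter-optimization studies.
#'
#' @param space Named list; each element a vector of candidate values for
#'   one `model_config` argument.
#' @param trials Number of sampled configurations (>= 1).
#' @param train_graphs,val_graphs Labelled graph lists.
#' @param feature_dim Node feature dimension.
#' @param seed RNG seed for sampling; trial t trains with seed
#'   `seed + t`.
#' @return List with `best_config`, `best_val_mse` and `trials`
#'   (data.frame).
#' @export
random_search <- function(space, trials, train_graphs, val_graphs, feature_dim,
                          seed = 1L) {
  if (!is.list(space) || length(space) == 0L || is.null(names(space)) ||
      any(!nzchar(names(space)))) {
    gg_stop("gg_config_error", "space must be a non-empty named list of candidate values")
  }
  bad <- setdiff(names(space), names(formals(model_config)))
  if (length(bad) > 0) {
    gg_stop("gg_config_error", "unknown model_config field(s) in space: %s",
            paste(bad, collapse = ", "))
  }
  if (!is_count(trials)) gg_stop("gg_config_error", "trials must be a positive integer")
  draws <- with_seed(seed, {
    lapply(seq_len(trials), function(tr) {
      lapply(space, function(v) v[[sample.int(length(v), 1L)]])
    })
  })
  rows <- vector("list", trials)
  best_mse <- Inf
  best_cfg <- NULL
  for (tr in seq_len(trials)) {
    args <- draws[[tr]]
    args$seed <- as.integer(seed + tr)
    cfg <- do.call(model_config, args)
    fit <- train_model(init_model(cfg, feature_dim), train_graphs, val_graphs,
                       cfg = cfg)
    vmse <- fit$history$val_mse[fit$history$best_epoch]
    rows[[tr]] <- data.frame(trial = tr,
                             as.data.frame(draws[[tr]], stringsAsFactors = FALSE),
                             val_mse = vmse)
    if (vmse < best_mse) {
      best_mse <- vmse
      best_cfg <- cfg
    }
  }
  list(best_config = best_cfg, best_val_mse = best_mse,
       trials = do.call(rbind, rows))
}

#' Save and load model checkpoints
#'
#' The checkpoint itself is an opaque serialized object; a plain-text JSON
#' sidecar (`<path>.json`) records the configuration, feature dimension,
#' seed, parameter checksum and package version so a run can be audited
#' without deserializing.  `load_checkpoint` verifies the sidecar
#' checksum and raises an integrity error on mismatch or corruption.
#'
#' @param model A `gg_model`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint`: the restored `gg_model`, reproducing
#'   predictions bit-identically.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "gg_model")) gg_stop("gg_contract_error", "model must be a gg_model")
  saveRDS(model, path)
  theta <- unlist(model$params, use.names = FALSE)
  sidecar <- list(
    package = "guidegraph",
    version = as.character(utils::packageVersion("guidegraph")),
    class = "gg_model",
    feature_dim = model$feature_dim,
    seed = model$config$seed,
    n_params = length(theta),
    param_sum = sum(theta),
    config = unclass(model$config)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) gg_stop("gg_integrity_error", "no such checkpoint: %s", path)
  model <- tryCatch(readRDS(path), error = function(e) {
    gg_stop("gg_integrity_error", "corrupted checkpoint %s: %s", path,
            conditionMessage(e))
  })
  if (!inherits(model, "gg_model")) {
    gg_stop("gg_integrity_error", "%s does not contain a gg_model", path)
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    theta <- unlist(model$params, use.names = FALSE)
    if (!identical(as.integer(sc$feature_dim), model$feature_dim)) {
      gg_stop("gg_integrity_error",
              "checkpoint %s: sidecar feature_dim %s != stored model feature_dim %d",
              path, sc$feature_dim, model$feature_dim)
    }
    if (length(theta) != sc$n_params ||
        abs(sum(theta) - sc$param_sum) > 1e-6 * max(1, abs(sc$param_sum))) {
      gg_stop("gg_integrity_error",
              "checkpoint %s fails its sidecar checksum; file may be corrupted", path)
    }
  }
  model
}
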