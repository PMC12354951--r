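#' Model configuration for the guide-graph regression network
#'
#' The network is a three-stage graph regressor: a per-node feed-forward
#' transform (NodeMLP), multi-head graph attention (incoming attention per
#' node softmax-normalized, heads concatenated), graph convolution
#' (sum aggregation over neighbors plus self), a global pooling readout
#' and a feed-forward regression head emitting the efficiency percent.
#' Sinusoidal positional channels are appended to the node features so the
#' network can express position-specific nucleotide effects along the
#' backbone chain.
#'
#' @param node_mlp_layers Layers in the per-node MLP (>= 1).
#' @param hidden_dim Hidden width; must be divisible by
#'   `attention_heads`.
#' @param attention_heads Attention heads per attention layer.
#' @param attention_layers Number of graph-attention layers (>= 1).
#' @param conv_layers Number of graph-convolution layers (>= 1).
#' @param dropout Dropout fraction in \[0, 1), active only during
#'   training.
#' @param pooling Graph readout: `"mean"`, `"sum"` or `"max"`.
#' @param head_layers Layers in the regression head (>= 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (graphs per step).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation MSE (epochs);
#'   0 disables tolerance for non-improving epochs.
#' @param seed Seed governing initialization, shuffling and dropout.
#' @param positional_dim Number of positional channels appended to node
#'   features (0 disables; default 9 = relative position + 4 sin/cos
#'   pairs).
#' @export
model_config <- function(node_mlp_layers = 2L, hidden_dim = 128L,
                         attention_heads = 4L, attention_layers = 1L,
                         conv_layers = 1L, dropout = 0.1,
                         pooling = c("mean", "sum", "max"), head_layers = 2L,
                         learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 100L, patience = 10L, seed = 1L,
                         positional_dim = 9L) {
  pooling <- match.arg(pooling)
  for (nm in c("node_mlp_layers", "hidden_dim", "attention_heads",
               "attention_layers", "conv_layers", "head_layers",
               "batch_size", "max_epochs")) {
    if (!is_count(get(nm))) gg_stop("gg_config_error", "%s must be a positive integer", nm)
  }
  if (!is.numeric(patience) || patience < 0) {
    gg_stop("gg_config_error", "patience must be >= 0")
  }
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    gg_stop("gg_config_error", "dropout must be in [0, 1)")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    gg_stop("gg_config_error", "learning_rate must be positive")
  }
  if (hidden_dim %% attention_heads != 0L) {
    gg_stop("gg_config_error", "hidden_dim (%d) must be divisible by attention_heads (%d)",
            hidden_dim, attention_heads)
  }
  if (!is.numeric(positional_dim) || positional_dim < 0) {
    gg_stop("gg_config_error", "positional_dim must be >= 0")
  }
  structure(list(node_mlp_layers = as.integer(node_mlp_layers),
                 hidden_dim = as.integer(hidden_dim),
                 attention_heads = as.integer(attention_heads),
                 attention_layers = as.integer(attention_layers),
                 conv_layers = as.integer(conv_layers), dropout = dropout,
                 pooling = pooling, head_layers = as.integer(head_layers),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed), positional_dim = as.integer(positional_dim)),
            class = "model_config")
}

#' @noRd
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a guide-graph regression model
#'
#' Parameters are initialized deterministically from `cfg$seed`
#' (Glorot-uniform weights, zero biases): the same configuration and seed
#' give bit-identical initial parameters.
#'
#' @param cfg A [model_config()].
#' @param feature_dim Node feature dimension the model accepts (e.g. 4 for
#'   one-hot).
#' @return A `gg_model`.
#' @export
init_model <- function(cfg, feature_dim) {
  if (!inherits(cfg, "model_config")) gg_stop("gg_config_error", "cfg must be a model_config")
  if (!is_count(feature_dim)) {
    gg_stop("gg_config_error", "feature_dim must be a positive integer")
  }
  feature_dim <- as.integer(feature_dim)
  h <- cfg$hidden_dim
  hk <- h %/% cfg$attention_heads
  in_dim <- feature_dim + cfg$positional_dim
  params <- with_seed(cfg$seed, {
    mlp <- vector("list", cfg$node_mlp_layers)
    d <- in_dim
    for (l in seq_len(cfg$node_mlp_layers)) {
      mlp[[l]] <- list(W = glorot(d, h), b = numeric(h))
      d <- h
    }
    gat <- vector("list", cfg$attention_layers)
    for (l in seq_len(cfg$attention_layers)) {
      heads <- lapply(seq_len(cfg$attention_heads), function(k) {
        list(W = glorot(h, hk),
             a_src = stats::runif(hk, -sqrt(3 / hk), sqrt(3 / hk)),
             a_dst = stats::runif(hk, -sqrt(3 / hk), sqrt(3 / hk)))
      })
      gat[[l]] <- list(heads = heads, b = numeric(h))
    }
    conv <- lapply(seq_len(cfg$conv_layers), function(l) {
      list(W = glorot(h, h), b = numeric(h))
    })
    hd <- max(4L, h %/% 2L)
    head_dims <- if (cfg$head_layers == 1L) c(h, 1L) else c(h, rep(hd, cfg$head_layers - 1L), 1L)
    head <- lapply(seq_len(cfg$head_layers), function(l) {
      list(W = glorot(head_dims[l], head_dims[l + 1L]), b = numeric(head_dims[l + 1L]))
    })
    list(mlp = mlp, gat = gat, conv = conv, head = head)
  })
  structure(list(config = cfg, feature_dim = feature_dim, params = params,
                 history = NULL),
            class = "gg_model")
}

#' @export
print.gg_model <- function(x, ...) {
  n_par <- length(unlist(x$params))
  cat(sprintf(paste0("<gg_model> feature_dim=%d, hidden=%d, %d attention layer(s) x %d head(s),",
                     " %d conv layer(s), %s pooling, %d parameters%s\n"),
              x$feature_dim, x$config$hidden_dim, x$config$attention_layers,
              x$config$attention_heads, x$config$conv_layers, x$config$pooling,
              n_par,
              if (is.null(x$history)) " (untrained)"
              else sprintf(", trained (best epoch %d)", x$history$best_epoch)))
  invisible(x)
}

#' @noRd
positional_encoding <- function(pos, len, dim) {
  n <- length(pos)
  if (dim == 0L) return(matrix(0, n, 0L))
  out <- matrix(0, n, dim)
  out[, 1L] <- ifelse(len > 1L, pos / pmax(len - 1L, 1L), 0)
  j <- 2L; m <- 0L
  while (j <= dim) {
    w <- 3^(-m)
    out[, j] <- sin(pos * w)
    if (j + 1L <= dim) out[, j + 1L] <- cos(pos * w)
    j <- j + 2L; m <- m + 1L
  }
  out
}

# Collate a list of guide_graphs into one block-diagonal batch.
# Arc indices become 1-based global; self-loops are appended for both the
# attention softmax (so isolated nodes attend to themselves) and the
# convolution aggregation.
#' @noRd
make_batch <- function(graphs, feature_dim) {
  sizes <- integer(length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (!inherits(g, "guide_graph")) {
      gg_stop("gg_contract_error", "element %d is not a guide_graph", i)
    }
    if (ncol(g$node_features) != feature_dim) {
      gg_stop("gg_contract_error",
              "graph %d ('%s'): feature dimension %d does not match model feature_dim %d",
              i, g$meta$id, ncol(g$node_features), feature_dim)
    }
    sizes[i] <- g$meta$n_nodes
  }
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  N <- sum(sizes)
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  src <- unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$arcs$src + 1L + offsets[i]),
                use.names = FALSE)
  dst <- unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$arcs$dst + 1L + offsets[i]),
                use.names = FALSE)
  arc_graph <- unlist(lapply(seq_along(graphs), function(i) rep(i, nrow(graphs[[i]]$arcs))),
                      use.names = FALSE)
  loops <- seq_len(N)
  list(
    X = X, N = N, G = length(graphs), sizes = sizes,
    graph_id = rep(seq_along(graphs), sizes),
    pos = unlist(lapply(graphs, function(g) g$positions %||% (0L:(g$meta$n_nodes - 1L))),
                 use.names = FALSE),
    len = rep(sizes, sizes),
    arc_src = src, arc_dst = dst, arc_graph = arc_graph,
    asrc = c(src, loops), adst = c(dst, loops),  # arcs + self-loops
    labels = vapply(graphs, `[[`, numeric(1), "label")
  )
}

#' @noRd
relu <- function(x) (x > 0) * x

# Forward pass over a batch.  Returns predictions, a cache for backprop
# (when keep_cache) and per-layer/head attention weights over `asrc/adst`
# arcs (when return_attention).  Dropout masks are drawn from the current
# RNG stream only when training = TRUE.
#' @noRd
nn_forward <- function(model, batch, training = FALSE, keep_cache = FALSE,
                       return_attention = FALSE) {
  cfg <- model$config
  p <- model$params
  N <- batch$N
  drop_p <- if (training) cfg$dropout else 0
  new_mask <- function() {
    if (drop_p > 0) {
      (matrix(stats::runif(N * cfg$hidden_dim), N) >= drop_p) / (1 - drop_p)
    } else NULL
  }
  cache <- list(masks = list())
  H <- cbind(batch$X, positional_encoding(batch$pos, batch$len, cfg$positional_dim))
  cache$mlp_in <- list()
  for (l in seq_along(p$mlp)) {
    cache$mlp_in[[l]] <- H
    A <- H %*% p$mlp[[l]]$W
    A <- sweep(A, 2L, p$mlp[[l]]$b, "+")
    H <- relu(A)
  }
  m <- new_mask()
  cache$masks$mlp <- m
  if (!is.null(m)) H <- H * m
  s <- batch$asrc; t <- batch$adst
  attn_out <- if (return_attention) vector("list", length(p$gat)) else NULL
  cache$gat <- list()
  for (l in seq_along(p$gat)) {
    layer <- p$gat[[l]]
    hc <- list(Hin = H, heads = list())
    parts <- vector("list", length(layer$heads))
    if (return_attention) attn_out[[l]] <- vector("list", length(layer$heads))
    for (k in seq_along(layer$heads)) {
      hp <- layer$heads[[k]]
      Z <- H %*% hp$W
      q <- drop(Z %*% hp$a_src)
      r <- drop(Z %*% hp$a_dst)
      pre <- q[s] + r[t]
      lr <- ifelse(pre > 0, pre, 0.2 * pre)
      mx <- group_max(lr, t, N)
      ex <- exp(lr - mx[t])
      den <- drop(rowsum(ex, t))
      alpha <- ex / den[t]
      Out <- rowsum(alpha * Z[s, , drop = FALSE], t)
      parts[[k]] <- Out
      hc$heads[[k]] <- list(Z = Z, pre = pre, alpha = alpha)
      if (return_attention) attn_out[[l]][[k]] <- alpha
    }
    C <- do.call(cbind, parts)
    A <- sweep(C, 2L, layer$b, "+")
    Hout <- relu(A)
    hc$A_pos <- A > 0
    mk <- new_mask()
    hc$mask <- mk
    if (!is.null(mk)) Hout <- Hout * mk
    cache$gat[[l]] <- hc
    H <- Hout
  }
  cache$conv <- list()
  for (l in seq_along(p$conv)) {
    Agg <- rowsum(H[s, , drop = FALSE], t)
    A <- Agg %*% p$conv[[l]]$W
    A <- sweep(A, 2L, p$conv[[l]]$b, "+")
    Hout <- relu(A)
    mk <- new_mask()
    cache$conv[[l]] <- list(Hin = H, Agg = Agg, A_pos = A > 0, mask = mk)
    if (!is.null(mk)) Hout <- Hout * mk
    H <- Hout
  }
  # readout
  if (cfg$pooling == "mean") {
    P <- rowsum(H, batch$graph_id) / batch$sizes
  } else if (cfg$pooling == "sum") {
    P <- rowsum(H, batch$graph_id)
  } else {
    P <- matrix(0, batch$G, ncol(H))
    amax <- matrix(0L, batch$G, ncol(H))
    for (cix in seq_len(ncol(H))) {
      o <- order(batch$graph_id, H[, cix])
      idx <- integer(batch$G)
      idx[batch$graph_id[o]] <- o
      amax[, cix] <- idx
      P[, cix] <- H[idx, cix]
    }
    cache$pool_argmax <- amax
  }
  cache$H_nodes <- H
  cache$head_in <- list()
  Hp <- P
  for (l in seq_along(p$head)) {
    cache$head_in[[l]] <- Hp
    A <- Hp %*% p$head[[l]]$W
    A <- sweep(A, 2L, p$head[[l]]$b, "+")
    Hp <- if (l < length(p$head)) relu(A) else A
  }
  pred <- drop(Hp)
  list(pred = pred,
       cache = if (keep_cache) cache else NULL,
       attention = attn_out)
}

# Backward pass: gradients of 0.5-free MSE-style upstream gradient dpred
# with respect to all parameters.  Mirrors nn_forward exactly.
#' @noRd
nn_backward <- function(model, batch, cache, dpred) {
  cfg <- model$config
  p <- model$params
  N <- batch$N
  s <- batch$asrc; t <- batch$adst
  g <- list(mlp = list(), gat = list(), conv = list(), head = list())
  # head
  dH <- matrix(dpred, ncol = 1L)
  for (l in rev(seq_along(p$head))) {
    Hin <- cache$head_in[[l]]
    if (l < length(p$head)) {
      # recompute activation mask from the stored input of the next layer
      A_out <- cache$head_in[[l + 1L]]
      dH <- dH * (A_out > 0)
    }
    g$head[[l]] <- list(W = crossprod(Hin, dH), b = colSums(dH))
    dH <- dH %*% t(p$head[[l]]$W)
  }
  dP <- dH
  # readout
  if (cfg$pooling == "mean") {
    dHn <- dP[batch$graph_id, , drop = FALSE] / batch$len
  } else if (cfg$pooling == "sum") {
    dHn <- dP[batch$graph_id, , drop = FALSE]
  } else {
    dHn <- matrix(0, N, ncol(dP))
    for (cix in seq_len(ncol(dP))) {
      idx <- cache$pool_argmax[, cix]
      dHn[idx, cix] <- dHn[idx, cix] + dP[, cix]
    }
  }
  # conv layers
  for (l in rev(seq_along(p$conv))) {
    cc <- cache$conv[[l]]
    if (!is.null(cc$mask)) dHn <- dHn * cc$mask
    dA <- dHn * cc$A_pos
    g$conv[[l]] <- list(W = crossprod(cc$Agg, dA), b = colSums(dA))
    dAgg <- dA %*% t(p$conv[[l]]$W)
    dHn <- rowsum(dAgg[t, , drop = FALSE], s)
  }
  # attention layers
  hk <- cfg$hidden_dim %/% cfg$attention_heads
  for (l in rev(seq_along(p$gat))) {
    lc <- cache$gat[[l]]
    layer <- p$gat[[l]]
    if (!is.null(lc$mask)) dHn <- dHn * lc$mask
    dA <- dHn * lc$A_pos
    db <- colSums(dA)
    dHin <- matrix(0, N, ncol(lc$Hin))
    gheads <- vector("list", length(layer$heads))
    for (k in seq_along(layer$heads)) {
      hp <- layer$heads[[k]]
      hcache <- lc$heads[[k]]
      cols <- ((k - 1L) * hk + 1L):(k * hk)
      dOut <- dA[, cols, drop = FALSE]
      Z <- hcache$Z
      alpha <- hcache$alpha
      dalpha <- rowSums(dOut[t, , drop = FALSE] * Z[s, , drop = FALSE])
      dZ <- rowsum(alpha * dOut[t, , drop = FALSE], s)
      ssum <- drop(rowsum(alpha * dalpha, t))
      de <- alpha * (dalpha - ssum[t])
      dpre <- de * ifelse(hcache$pre > 0, 1, 0.2)
      dq <- drop(rowsum(dpre, s, reorder = TRUE))
      # rowsum over src: not all nodes need appear as src of an arc+loop set;
      # loops guarantee they do, so dq/dr align with 1..N
      dr <- drop(rowsum(dpre, t))
      da_src <- drop(crossprod(Z, dq))
      da_dst <- drop(crossprod(Z, dr))
      dZ <- dZ + outer(dq, hp$a_src) + outer(dr, hp$a_dst)
      gheads[[k]] <- list(W = crossprod(lc$Hin, dZ), a_src = da_src, a_dst = da_dst)
      dHin <- dHin + dZ %*% t(hp$W)
    }
    g$gat[[l]] <- list(heads = gheads, b = db)
    dHn <- dHin
  }
  # node MLP
  if (!is.null(cache$masks$mlp)) dHn <- dHn * cache$masks$mlp
  for (l in rev(seq_along(p$mlp))) {
    Hin <- cache$mlp_in[[l]]
    A_out <- if (l < length(p$mlp)) cache$mlp_in[[l + 1L]] else NULL
    mask <- if (is.null(A_out)) {
      # last MLP layer: its post-relu output fed the first GAT layer input
      (if (length(cache$gat) > 0) cache$gat[[1L]]$Hin else cache$conv[[1L]]$Hin) > 0
    } else {
      A_out > 0
    }
    dA <- dHn * mask
    g$mlp[[l]] <- list(W = crossprod(Hin, dA), b = colSums(dA))
    dHn <- dA %*% t(p$mlp[[l]]$W)
  }
  g
}
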