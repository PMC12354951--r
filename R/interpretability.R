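# Attention-based per-position importance profiles: which spacer
# positions receive, emit and concentrate attention mass across a set of
# guide graphs.

#' Extract arc attention weights from a trained model
#'
#' Runs the deterministic forward pass on each graph and collects the
#' attention weights of the final attention layer (heads averaged by
#' default).  Weights cover all arcs plus the implicit self-loops; each
#' node's incoming weights sum to 1.
#'
#' @param model A `gg_model`.
#' @param graphs List of `guide_graph`s.
#' @param average_heads Average over heads (default) or keep per-head
#'   weights.
#' @param layer Attention layer index, or `"last"` (default).
#' @return List (one element per graph) of data.frames with columns
#'   `src`, `dst` (0-based) and `weight` (or `weight.h1`, ... when
#'   `average_heads = FALSE`), each with attribute `n_nodes`.
#' @export
extract_attention <- function(model, graphs, average_heads = TRUE, layer = "last") {
  if (!inherits(model, "gg_model")) gg_stop("gg_contract_error", "model must be a gg_model")
  if (model$config$attention_layers < 1L) {
    gg_stop("gg_contract_error", "model has no attention layer")
  }
  li <- if (identical(layer, "last")) model$config$attention_layers else as.integer(layer)
  if (li < 1L || li > model$config$attention_layers) {
    gg_stop("gg_config_error", "layer must be in 1..%d", model$config$attention_layers)
  }
  lapply(graphs, function(g) {
    fw <- model_forward(model, g, return_attention = TRUE)
    heads <- fw$attention[[li]]
    base <- heads[[1L]][c("src", "dst")]
    if (average_heads) {
      w <- rowMeans(do.call(cbind, lapply(heads, `[[`, "weight")))
      out <- cbind(base, weight = w)
    } else {
      ws <- do.call(cbind, lapply(heads, `[[`, "weight"))
      colnames(ws) <- sprintf("weight.h%d", seq_along(heads))
      out <- cbind(base, ws)
    }
    attr(out, "n_nodes") <- g$meta$n_nodes
    out
  })
}

#' Per-position attention importance profile
#'
#' For graphs of a common length (spacer-only mode), aggregates attention
#' into three per-position scores: `incoming` (mean over graphs of total
#' attention received by the position), `outgoing` (mean total attention
#' emitted), and `combined` (the product of the normalized incoming and
#' outgoing scores, renormalized) which highlights hub positions high in
#' both.  Normalized variants sum to 1 over positions.
#'
#' @param attn Output of [extract_attention()] (head-averaged).
#' @param length Common graph length; checked against every element.
#' @return An `attention_profile` data.frame with columns `position`
#'   (0-based, 5'->3'), `incoming`, `outgoing`, `combined`,
#'   `incoming_norm`, `outgoing_norm`, `combined_norm`.
#' @export
position_importance <- function(attn, length) {
  if (length(attn) == 0L) gg_stop("gg_contract_error", "no attention data supplied")
  if (!is_count(length)) gg_stop("gg_config_error", "length must be a positive integer")
  lens <- vapply(attn, function(a) attr(a, "n_nodes") %||% (max(a$src, a$dst) + 1L),
                 numeric(1))
  if (any(lens != length)) {
    gg_stop("gg_contract_error",
            "mixed graph lengths (%s): position profiles need a common length",
            paste(unique(lens), collapse = ", "))
  }
  inc <- matrix(0, length(attn), length)
  out <- matrix(0, length(attn), length)
  for (i in seq_along(attn)) {
    a <- attn[[i]]
    if (!"weight" %in% names(a)) {
      gg_stop("gg_contract_error", "attention must be head-averaged (column 'weight')")
    }
    by_dst <- rowsum(a$weight, a$dst)
    inc[i, as.integer(rownames(by_dst)) + 1L] <- drop(by_dst)
    by_src <- rowsum(a$weight, a$src)
    out[i, as.integer(rownames(by_src)) + 1L] <- drop(by_src)
  }
  incoming <- colMeans(inc)
  outgoing <- colMeans(out)
  inc_n <- incoming / sum(incoming)
  out_n <- outgoing / sum(outgoing)
  comb <- inc_n * out_n
  prof <- data.frame(position = 0:(length - 1L),
                     incoming = incoming, outgoing = outgoing,
                     combined = comb,
                     incoming_norm = inc_n, outgoing_norm = out_n,
                     combined_norm = comb / sum(comb))
  class(prof) <- c("attention_profile", "data.frame")
  prof
}

#' Rank positions by importance score
#'
#' Stable descending sort per score type; ties broken by ascending
#' position.
#'
#' @param profile An [position_importance()] profile.
#' @return Named list of integer vectors (`incoming`, `outgoing`,
#'   `combined`), each the 0-based positions from most to least
#'   important.
#' @export
rank_positions <- function(profile) {
  if (!inherits(profile, "attention_profile")) {
    gg_stop("gg_contract_error", "profile must be an attention_profile")
  }
  rank_one <- function(score) profile$position[order(-score, profile$position)]
  list(incoming = rank_one(profile$incoming),
       outgoing = rank_one(profile$outgoing),
       combined = rank_one(profile$combined))
}

#' @export
print.attention_profile <- function(x, ...) {
  cat(sprintf("<attention_profile> %d positions; top combined: %s\n",
              nrow(x), paste(utils::head(rank_positions(x)$combined, 5L), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}
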