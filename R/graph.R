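#' A single guide RNA record
#'
#' The record unit of the toolkit: an id, a spacer (or scaffold-extended)
#' sequence 5'->3', an optional editing efficiency on the 0-100 percent
#' scale, and an optional secondary structure.
#'
#' @param id Record identifier.
#' @param sequence RNA sequence (DNA T is normalized to U, case-folded).
#' @param efficiency Editing efficiency percent in \[0, 100\], or `NA`.
#' @param structure Optional `secondary_structure` (see
#'   [parse_dot_bracket()]).
#' @param ambiguity `"strict"` rejects ambiguity codes; `"uniform"` admits
#'   them (they one-hot-encode as 0.25 rows).
#' @export
guide_record <- function(id, sequence, efficiency = NA_real_, structure = NULL,
                         ambiguity = c("strict", "uniform")) {
  ambiguity <- match.arg(ambiguity)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    gg_stop("gg_format_error", "id must be a non-empty string")
  }
  sequence <- normalize_rna(sequence, ambiguity, what = sprintf("sequence of '%s'", id))
  if (!is.na(efficiency)) {
    if (!is.numeric(efficiency) || length(efficiency) != 1L ||
        efficiency < 0 || efficiency > 100) {
      gg_stop("gg_format_error",
              "efficiency of '%s' must be in [0, 100] percent, got %s",
              id, format(efficiency))
    }
  }
  if (!is.null(structure)) {
    if (!inherits(structure, "secondary_structure")) {
      gg_stop("gg_format_error", "structure of '%s' must be a secondary_structure", id)
    }
    if (structure$length != nchar(sequence)) {
      gg_stop("gg_contract_error",
              "record '%s': structure length %d != sequence length %d",
              id, structure$length, nchar(sequence))
    }
  }
  structure(list(id = id, sequence = sequence,
                 efficiency = as.numeric(efficiency), structure = structure),
            class = "guide_record")
}

#' @export
print.guide_record <- function(x, ...) {
  cat(sprintf("<guide_record> %s  %s  efficiency=%s  structure=%s\n",
              x$id, x$sequence,
              if (is.na(x$efficiency)) "NA" else format(x$efficiency),
              if (is.null(x$structure)) "absent" else x$structure$dot_bracket))
  invisible(x)
}

#' Graph construction configuration
#'
#' @param mode `"spacer_only"` (20-nt target-matching sequence) or
#'   `"extended"` (spacer plus scaffold, e.g. 20 + 75 nt; the extended
#'   sequence is taken from the input as given).
#' @param ambiguity_policy `"strict"` or `"uniform"`.
#' @param feature_provider `"one_hot"` or `"embedding"`.
#' @export
graph_build_config <- function(mode = c("spacer_only", "extended"),
                               ambiguity_policy = c("strict", "uniform"),
                               feature_provider = c("one_hot", "embedding")) {
  structure(list(mode = match.arg(mode),
                 ambiguity_policy = match.arg(ambiguity_policy),
                 feature_provider = match.arg(feature_provider)),
            class = "graph_build_config")
}

#' One-hot node features
#'
#' @param seq RNA sequence.
#' @param ambiguity `"strict"` errors on ambiguity codes; `"uniform"`
#'   encodes them as rows of 0.25.
#' @return Numeric matrix, one row per nucleotide, columns `A`, `C`, `G`,
#'   `U` in fixed order; every row sums to 1.
#' @export
one_hot_features <- function(seq, ambiguity = c("strict", "uniform")) {
  ambiguity <- match.arg(ambiguity)
  seq <- normalize_rna(seq, ambiguity)
  chars <- rna_chars(seq)
  n <- length(chars)
  m <- matrix(0, n, 4L, dimnames = list(NULL, RNA_ALPHABET))
  known <- chars %in% RNA_ALPHABET
  m[cbind(which(known), match(chars[known], RNA_ALPHABET))] <- 1
  if (any(!known)) m[!known, ] <- 0.25
  m
}

#' Read per-nucleotide embedding matrices from a block text file
#'
#' Format: one block per record, introduced by a shape header line
#' `>id nrow ncol`, followed by `nrow` whitespace-delimited numeric rows of
#' `ncol` values.  Such files stand in for per-nucleotide embeddings
#' produced by external RNA language models.
#'
#' @param path Embedding file path.
#' @param ids Character vector of record ids to resolve; all must be
#'   present.
#' @param lengths Optional integer vector (parallel to `ids`) of sequence
#'   lengths; when given, each matrix's row count is checked against it.
#' @return Named list of matrices, one per id, in the order of `ids`.
#' @export
load_embedding_features <- function(path, ids, lengths = NULL) {
  if (length(ids) == 0L) return(stats::setNames(list(), character(0)))
  if (!file.exists(path)) gg_stop("gg_format_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  mats <- list()
  k <- 1L
  while (k <= length(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line)) { k <- k + 1L; next }
    if (!startsWith(line, ">")) {
      gg_stop("gg_format_error",
              "embedding file %s, line %d: expected a '>id nrow ncol' header", path, k)
    }
    hdr <- strsplit(sub("^>\\s*", "", line), "\\s+")[[1]]
    if (length(hdr) != 3L) {
      gg_stop("gg_format_error",
              "embedding file %s, line %d: header must be '>id nrow ncol'", path, k)
    }
    id <- hdr[1L]
    nr <- suppressWarnings(as.integer(hdr[2L]))
    nc <- suppressWarnings(as.integer(hdr[3L]))
    if (is.na(nr) || is.na(nc) || nr < 1L || nc < 1L) {
      gg_stop("gg_format_error",
              "embedding file %s: invalid shape header for '%s'", path, id)
    }
    if (k + nr > length(lines)) {
      gg_stop("gg_format_error",
              "embedding file %s: truncated block for '%s'", path, id)
    }
    block <- lines[(k + 1L):(k + nr)]
    vals <- lapply(block, function(l) suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    if (any(vapply(vals, length, integer(1)) != nc) || anyNA(unlist(vals))) {
      gg_stop("gg_format_error",
              "embedding file %s: malformed numeric block for '%s' (declared %dx%d)",
              path, id, nr, nc)
    }
    mats[[id]] <- matrix(unlist(vals), nrow = nr, ncol = nc, byrow = TRUE)
    k <- k + nr + 1L
  }
  missing <- setdiff(ids, names(mats))
  if (length(missing) > 0) {
    gg_stop("gg_format_error", "embedding file %s: missing id(s): %s",
            path, paste(missing, collapse = ", "))
  }
  out <- mats[ids]
  if (!is.null(lengths)) {
    for (i in seq_along(ids)) {
      if (nrow(out[[i]]) != lengths[i]) {
        gg_stop("gg_contract_error",
                "record '%s': embedding has %d rows but sequence has %d nucleotides",
                ids[i], nrow(out[[i]]), lengths[i])
      }
    }
  }
  out
}

#' @rdname load_embedding_features
#' @param mats Named list of matrices to write.
#' @export
write_embedding_features <- function(mats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(mats)) {
    m <- mats[[id]]
    writeLines(sprintf(">%s %d %d", id, nrow(m), ncol(m)), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Build the typed arc list for a guide graph
#'
#' Sequential edges connect consecutive nucleotides (the phosphodiester
#' backbone); structural edges connect the base pairs of the secondary
#' structure.  Each undirected edge is emitted as two reciprocal directed
#' arcs.  Arcs are ordered sequential-first, then structural, each block
#' ascending by `(src, dst)`, so rebuilding from identical inputs is
#' bit-stable.
#'
#' @param length Number of nucleotides (nodes).
#' @param s A `secondary_structure` of the same length.
#' @return data.frame with integer columns `src`, `dst` (0-based) and
#'   character column `type` (`"sequential"` or `"structural"`).
#' @export
build_edges <- function(length, s) {
  if (!is_count(length, min = 1L)) {
    gg_stop("gg_contract_error", "length must be a positive integer")
  }
  length <- as.integer(length)
  if (s$length != length) {
    gg_stop("gg_contract_error", "structure length %d != requested length %d",
            s$length, length)
  }
  if (nrow(s$pairs) > 0 && max(s$pairs) >= length) {
    gg_stop("gg_contract_error", "pair index %d out of range for length %d",
            max(s$pairs), length)
  }
  if (length >= 2L) {
    p <- 0L:(length - 2L)
    seq_src <- c(rbind(p, p + 1L))
    seq_dst <- c(rbind(p + 1L, p))
    seq_arcs <- data.frame(src = seq_src, dst = seq_dst, type = "sequential")
    seq_arcs <- seq_arcs[order(seq_arcs$src, seq_arcs$dst), , drop = FALSE]
  } else {
    seq_arcs <- data.frame(src = integer(0), dst = integer(0), type = character(0))
  }
  pr <- s$pairs
  if (nrow(pr) > 0) {
    keep <- abs(pr[, 2L] - pr[, 1L]) >= 2L  # adjacent pairs duplicate backbone arcs
    pr <- pr[keep, , drop = FALSE]
  }
  if (nrow(pr) > 0) {
    str_arcs <- data.frame(src = c(pr[, 1L], pr[, 2L]),
                           dst = c(pr[, 2L], pr[, 1L]),
                           type = "structural")
    str_arcs <- str_arcs[order(str_arcs$src, str_arcs$dst), , drop = FALSE]
  } else {
    str_arcs <- data.frame(src = integer(0), dst = integer(0), type = character(0))
  }
  out <- rbind(seq_arcs, str_arcs)
  rownames(out) <- NULL
  out
}

#' Build a guide graph from a record, features and a structure
#'
#' Nodes are nucleotides (node count equals sequence length); arcs come
#' from [build_edges()]; the efficiency label, when present, is copied
#' onto the graph.
#'
#' @param rec A [guide_record()].
#' @param cfg A [graph_build_config()].
#' @param features Node feature matrix (rows = nucleotides).  Defaults to
#'   one-hot encoding of the record's sequence.
#' @param s A `secondary_structure`.  Defaults to the record's structure,
#'   or to [predict_structure()] when the record carries none.
#' @return A `guide_graph`: list with `node_features`, `arcs`, `label`,
#'   `meta` (id, provider, mode, n_nodes).
#' @export
build_graph <- function(rec, cfg = graph_build_config(), features = NULL, s = NULL) {
  if (!inherits(rec, "guide_record")) {
    gg_stop("gg_contract_error", "rec must be a guide_record")
  }
  n <- nchar(rec$sequence)
  if (is.null(s)) {
    s <- rec$structure %||% predict_structure(rec$sequence)
  }
  if (s$length != n) {
    gg_stop("gg_contract_error",
            "record '%s': structure length %d != sequence length %d",
            rec$id, s$length, n)
  }
  provider <- cfg$feature_provider
  if (is.null(features)) {
    features <- one_hot_features(rec$sequence, cfg$ambiguity_policy)
    provider <- "one_hot"
  }
  features <- as.matrix(features)
  if (nrow(features) != n) {
    gg_stop("gg_contract_error",
            "record '%s': feature matrix has %d rows but sequence has %d nucleotides",
            rec$id, nrow(features), n)
  }
  if (!all(is.finite(features))) {
    gg_stop("gg_contract_error", "record '%s': non-finite node features", rec$id)
  }
  structure(
    list(node_features = features,
         arcs = build_edges(n, s),
         positions = 0:(n - 1L),  # 5'->3' nucleotide position of each node row
         label = rec$efficiency,
         meta = list(id = rec$id, provider = provider, mode = cfg$mode,
                     n_nodes = n)),
    class = "guide_graph"
  )
}

#' @export
print.guide_graph <- function(x, ...) {
  cat(sprintf("<guide_graph> %s: %d nodes, %d sequential + %d structural arcs, label=%s\n",
              x$meta$id, x$meta$n_nodes,
              sum(x$arcs$type == "sequential"), sum(x$arcs$type == "structural"),
              if (is.na(x$label)) "NA" else format(x$label)))
  invisible(x)
}

#' Drop structural arcs from a guide graph (edge-ablation switch)
#'
#' Returns the graph with only its backbone (sequential) arcs, for
#' structure-ablation experiments.
#'
#' @param g A `guide_graph`.
#' @export
drop_structural_edges <- function(g) {
  g$arcs <- g$arcs[g$arcs$type == "sequential", , drop = FALSE]
  rownames(g$arcs) <- NULL
  g
}

#' Build a dataset of guide graphs
#'
#' @param records List of [guide_record()]s.
#' @param cfg A [graph_build_config()].
#' @param structure_source `NULL` (use each record's structure, predicting
#'   with [predict_structure()] when absent), a named list of
#'   `secondary_structure`s keyed by record id, or a function
#'   `record -> secondary_structure`.
#' @param feature_source `NULL` (one-hot), a named list of feature matrices
#'   keyed by record id, or a function `record -> matrix`.
#' @param on_error `"stop"` propagates the first per-record error;
#'   `"skip"` drops failing records and reports them in the `"failures"`
#'   attribute.
#' @return List of `guide_graph`s, order-preserving, with attributes
#'   `failures` (data.frame of id/message) and `edge_summary`.
#' @export
build_dataset <- function(records, cfg = graph_build_config(),
                          structure_source = NULL, feature_source = NULL,
                          on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  graphs <- list()
  fail_id <- character(0); fail_msg <- character(0)
  for (rec in records) {
    res <- tryCatch({
      s <- if (is.null(structure_source)) {
        rec$structure %||% predict_structure(rec$sequence)
      } else if (is.function(structure_source)) {
        structure_source(rec)
      } else {
        structure_source[[rec$id]] %||%
          gg_stop("gg_contract_error", "no structure supplied for record '%s'", rec$id)
      }
      feats <- if (is.null(feature_source)) {
        NULL
      } else if (is.function(feature_source)) {
        feature_source(rec)
      } else {
        feature_source[[rec$id]] %||%
          gg_stop("gg_contract_error", "no features supplied for record '%s'", rec$id)
      }
      build_graph(rec, cfg, features = feats, s = s)
    }, guidegraph_error = function(e) e)
    if (inherits(res, "guidegraph_error")) {
      if (on_error == "stop") stop(res)
      fail_id <- c(fail_id, rec$id)
      fail_msg <- c(fail_msg, conditionMessage(res))
    } else {
      graphs[[length(graphs) + 1L]] <- res
    }
  }
  attr(graphs, "failures") <- data.frame(id = fail_id, message = fail_msg)
  n_seq <- sum(vapply(graphs, function(g) sum(g$arcs$type == "sequential"), numeric(1)))
  n_str <- sum(vapply(graphs, function(g) sum(g$arcs$type == "structural"), numeric(1)))
  attr(graphs, "edge_summary") <- c(sequential_arcs = n_seq, structural_arcs = n_str)
  graphs
}
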