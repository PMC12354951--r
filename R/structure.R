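#' RNA secondary structures in dot-bracket form
#'
#' A `secondary_structure` couples a dot-bracket string with the base-pair
#' set it encodes.  Pairs are stored as a two-column integer matrix of
#' 0-based indices `(i, j)` with `i < j`, reported 5'->3'.  Only round
#' brackets are supported; pseudoknot bracket families are rejected.
#'
#' @param dot_bracket Dot-bracket string over `.`, `(`, `)`.
#' @return A `secondary_structure` object with fields `length`,
#'   `dot_bracket` and `pairs`.
#' @examples
#' s <- parse_dot_bracket("((...))")
#' s$pairs
#' to_dot_bracket(s$pairs, s$length)
#' @export
parse_dot_bracket <- function(dot_bracket) {
  if (!is.character(dot_bracket) || length(dot_bracket) != 1L ||
      is.na(dot_bracket) || !nzchar(dot_bracket)) {
    gg_stop("gg_format_error", "dot-bracket string must be a single non-empty string")
  }
  chars <- strsplit(dot_bracket, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("[", "]", "{", "}", "<", ">"))) {
    gg_stop("gg_format_error",
            "pseudoknot bracket types are not supported; only '.', '(' and ')' are accepted")
  }
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad) > 0) {
    gg_stop("gg_format_error", "illegal character(s) in dot-bracket string: %s",
            paste(bad, collapse = ", "))
  }
  n <- length(chars)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  opens <- integer(n)  # preallocated stack
  top <- 0L
  i_list <- integer(0)
  j_list <- integer(0)
  for (p in seq_len(n)) {
    ch <- chars[p]
    if (ch == "(") {
      top <- top + 1L
      opens[top] <- p
    } else if (ch == ")") {
      if (top == 0L) {
        gg_stop("gg_format_error",
                "unbalanced dot-bracket string: ')' at position %d has no matching '('", p - 1L)
      }
      i_list <- c(i_list, opens[top])
      j_list <- c(j_list, p)
      top <- top - 1L
    }
  }
  if (top > 0L) {
    gg_stop("gg_format_error",
            "unbalanced dot-bracket string: %d unmatched '('", top)
  }
  if (length(i_list) > 0) {
    o <- order(i_list)
    pairs <- cbind(i = i_list[o] - 1L, j = j_list[o] - 1L)
  } else {
    pairs <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  }
  new_secondary_structure(n, dot_bracket, pairs)
}

#' @noRd
new_secondary_structure <- function(length, dot_bracket, pairs) {
  structure(
    list(length = as.integer(length), dot_bracket = dot_bracket,
         pairs = pairs),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> length %d, %d base pair(s)\n%s\n",
              x$length, nrow(x$pairs), x$dot_bracket))
  invisible(x)
}

#' Serialize a base-pair set to dot-bracket notation
#'
#' Inverse of [parse_dot_bracket()].  The pair set must be non-crossing
#' (nested); crossing pairs would require pseudoknot bracket families and
#' are rejected.
#'
#' @param pairs Two-column matrix (or data.frame) of 0-based index pairs.
#' @param length Number of nucleotides.
#' @return Dot-bracket string of `length` characters.
#' @export
to_dot_bracket <- function(pairs, length) {
  if (!is_count(length, min = 1L)) {
    gg_stop("gg_format_error", "length must be a positive integer")
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) return(strrep(".", length))
  if (ncol(pairs) != 2L) gg_stop("gg_format_error", "pairs must have two columns")
  storage.mode(pairs) <- "integer"
  i <- pmin(pairs[, 1L], pairs[, 2L])
  j <- pmax(pairs[, 1L], pairs[, 2L])
  if (any(i == j)) gg_stop("gg_format_error", "a base cannot pair with itself")
  if (any(i < 0L) || any(j >= length)) {
    gg_stop("gg_format_error", "pair index out of range for length %d", length)
  }
  idx <- c(i, j)
  if (anyDuplicated(idx)) {
    gg_stop("gg_format_error", "an index appears in more than one pair")
  }
  o <- order(i)
  i <- i[o]; j <- j[o]
  # nesting check via stack over close positions
  n <- nrow(pairs)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (i[b] < j[a] && j[b] > j[a]) {
          gg_stop("gg_pseudoknot_error",
                  "crossing pairs (%d,%d) and (%d,%d): pseudoknots are not supported",
                  i[a], j[a], i[b], j[b])
        }
      }
    }
  }
  chars <- rep(".", length)
  chars[i + 1L] <- "("
  chars[j + 1L] <- ")"
  paste(chars, collapse = "")
}

#' Base-pairing rules for structure validation and prediction
#'
#' Canonical Watson-Crick pairs plus the G-U wobble by default, with a
#' minimum hairpin-loop size of 3 unpaired bases (standard RNA
#' stereochemistry).
#'
#' @param allowed_pairs Character vector of allowed dinucleotide pairs
#'   (e.g. `"GC"`); must be symmetric.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @export
pairing_rules <- function(allowed_pairs = c("AU", "UA", "GC", "CG", "GU", "UG"),
                          min_loop = 3L) {
  if (!is.numeric(min_loop) || length(min_loop) != 1L || min_loop < 0 ||
      min_loop != as.integer(min_loop)) {
    gg_stop("gg_config_error", "min_loop must be a nonnegative integer")
  }
  allowed_pairs <- toupper(allowed_pairs)
  rev2 <- vapply(allowed_pairs, function(p) {
    paste(rev(strsplit(p, "")[[1]]), collapse = "")
  }, character(1))
  if (!all(rev2 %in% allowed_pairs)) {
    gg_stop("gg_config_error", "allowed_pairs must be symmetric (if XY then YX)")
  }
  structure(list(allowed_pairs = allowed_pairs, min_loop = as.integer(min_loop)),
            class = "pairing_rules")
}

#' Validate a secondary structure against a sequence and pairing rules
#'
#' @param seq RNA sequence string (T is normalized to U).
#' @param s A `secondary_structure`.
#' @param rules A [pairing_rules()] object.
#' @return A data.frame with one row per pair (`i`, `j`, `nt_i`, `nt_j`,
#'   `pair_allowed`, `loop_ok`) and attributes `pass` (logical).
#' @export
validate_structure <- function(seq, s, rules = pairing_rules()) {
  seq <- normalize_rna(seq, "uniform")
  if (nchar(seq) != s$length) {
    gg_stop("gg_contract_error",
            "sequence length %d does not match structure length %d",
            nchar(seq), s$length)
  }
  chars <- rna_chars(seq)
  np <- nrow(s$pairs)
  if (np == 0L) {
    rep_df <- data.frame(i = integer(0), j = integer(0),
                         nt_i = character(0), nt_j = character(0),
                         pair_allowed = logical(0), loop_ok = logical(0))
  } else {
    i <- s$pairs[, 1L]; j <- s$pairs[, 2L]
    nt_i <- chars[i + 1L]; nt_j <- chars[j + 1L]
    rep_df <- data.frame(
      i = i, j = j, nt_i = nt_i, nt_j = nt_j,
      pair_allowed = paste0(nt_i, nt_j) %in% rules$allowed_pairs,
      loop_ok = (j - i - 1L) >= rules$min_loop
    )
  }
  attr(rep_df, "pass") <- all(rep_df$pair_allowed & rep_df$loop_ok)
  rep_df
}

#' Predict a secondary structure by base-pair maximization
#'
#' Self-contained Nussinov-style dynamic program: returns a non-crossing
#' structure maximizing the number of allowed base pairs subject to the
#' minimum loop size.  It stands in for external deep-learning structure
#' predictors; externally predicted structures can be supplied instead as
#' dot-bracket files.  Traceback is deterministic: when leaving position i
#' unpaired achieves the optimum it is preferred, otherwise the smallest
#' pairing partner j is chosen.
#'
#' @param seq RNA sequence over A/C/G/U (T normalized to U; ambiguity codes
#'   are an error).
#' @param rules A [pairing_rules()] object.
#' @return A `secondary_structure`.
#' @examples
#' predict_structure("GGGAAACCC")$dot_bracket
#' @export
predict_structure <- function(seq, rules = pairing_rules()) {
  seq <- normalize_rna(seq, "strict")
  chars <- rna_chars(seq)
  n <- length(chars)
  min_loop <- rules$min_loop
  allowed <- rules$allowed_pairs
  if (n == 0L) gg_stop("gg_format_error", "empty sequence")
  # can_pair[i, j]: allowed pair with sufficient loop
  can <- matrix(FALSE, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      ok <- paste0(chars[i], chars[js]) %in% allowed & (js - i - 1L) >= min_loop
      can[i, js] <- ok
    }
  }
  M <- matrix(0L, n, n)
  if (n >= 2L) {
    for (span in 1L:(n - 1L)) {
      for (i in 1L:(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]                      # i unpaired
        ks <- which(can[i, (i + 1L):j]) + i
        for (k in ks) {
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
          cand <- 1L + inner + rest
          if (cand > best) best <- cand
        }
        M[i, j] <- best
      }
    }
  }
  # deterministic traceback on an explicit stack of [i, j] intervals
  i_out <- integer(0); j_out <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j) next
    if (M[i, j] == M[i + 1L, j]) {      # prefer leaving i unpaired
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    ks <- which(can[i, (i + 1L):j]) + i
    for (k in ks) {                     # smallest feasible partner first
      inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
      rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
      if (M[i, j] == 1L + inner + rest) {
        i_out <- c(i_out, i); j_out <- c(j_out, k)
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        if (i + 1L <= k - 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        break
      }
    }
  }
  if (length(i_out) > 0) {
    o <- order(i_out)
    pairs <- cbind(i = i_out[o] - 1L, j = j_out[o] - 1L)
  } else {
    pairs <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  }
  new_secondary_structure(n, to_dot_bracket(pairs, n), pairs)
}

#' Read and write Vienna-style dot-bracket structure files
#'
#' The canonical record is three lines: `>id`, sequence, dot-bracket.
#' Headerless two-line records (sequence then structure) are also accepted,
#' in which case ids `record_1`, `record_2`, ... are assigned.
#'
#' @param path File path.
#' @return `read_structure_file`: a named list with one element per record,
#'   each a list of `id`, `sequence` and `structure`
#'   (a [parse_dot_bracket()] result).
#' @export
read_structure_file <- function(path) {
  if (!file.exists(path)) gg_stop("gg_format_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  records <- list()
  if (startsWith(lines[1L], ">")) {
    if (length(lines) %% 3L != 0L) {
      gg_stop("gg_format_error",
              "structure file %s: expected triplets of header/sequence/structure lines", path)
    }
    for (r in seq_len(length(lines) / 3L)) {
      id <- sub("^>\\s*", "", lines[3L * r - 2L])
      seq <- trimws(lines[3L * r - 1L])
      db <- trimws(lines[3L * r])
      s <- parse_dot_bracket(db)
      if (nchar(seq) != s$length) {
        gg_stop("gg_format_error",
                "record '%s': sequence length %d != structure length %d",
                id, nchar(seq), s$length)
      }
      records[[id]] <- list(id = id, sequence = seq, structure = s)
    }
  } else {
    if (length(lines) %% 2L != 0L) {
      gg_stop("gg_format_error",
              "structure file %s: expected pairs of sequence/structure lines", path)
    }
    for (r in seq_len(length(lines) / 2L)) {
      id <- sprintf("record_%d", r)
      seq <- trimws(lines[2L * r - 1L])
      s <- parse_dot_bracket(trimws(lines[2L * r]))
      if (nchar(seq) != s$length) {
        gg_stop("gg_format_error",
                "record %d: sequence length %d != structure length %d",
                r, nchar(seq), s$length)
      }
      records[[id]] <- list(id = id, sequence = seq, structure = s)
    }
  }
  records
}

#' @rdname read_structure_file
#' @param records Named list as returned by `read_structure_file`, or a list
#'   of `guide_record`s carrying structures.
#' @export
write_structure_file <- function(records, path) {
  lines <- character(0)
  for (rec in records) {
    s <- rec$structure
    db <- if (inherits(s, "secondary_structure")) s$dot_bracket else s
    lines <- c(lines, paste0(">", rec$id), rec$sequence, db)
  }
  writeLines(lines, path)
  invisible(path)
}
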