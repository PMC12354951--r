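# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gg_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...)) > 0) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "guidegraph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never clobber user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

RNA_ALPHABET <- c("A", "C", "G", "U")

# Uppercase, DNA thymine -> uracil.  Ambiguity codes (anything outside ACGU)
# are rejected in strict mode; uniform mode lets them through for the feature
# layer to smear into 0.25 rows.
#' @noRd
normalize_rna <- function(seq, ambiguity = c("strict", "uniform"), what = "sequence") {
  ambiguity <- match.arg(ambiguity)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    gg_stop("gg_format_error", "%s must be a single non-empty string", what)
  }
  seq <- chartr("t", "u", toupper(seq))
  seq <- chartr("T", "U", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(RNA_ALPHABET, "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"))
  if (length(bad) > 0) {
    gg_stop("gg_format_error", "illegal character(s) in %s: %s", what,
            paste(bad, collapse = ", "))
  }
  if (ambiguity == "strict" && any(!chars %in% RNA_ALPHABET)) {
    gg_stop("gg_format_error",
            "ambiguity code(s) in %s under strict policy: %s", what,
            paste(setdiff(unique(chars), RNA_ALPHABET), collapse = ", "))
  }
  seq
}

#' @noRd
rna_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' @noRd
rna_complement <- function(chars) {
  unname(c(A = "U", U = "A", G = "C", C = "G")[chars])
}

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

# max of x within integer groups 1..ng (vectorised: ordered assignment,
# last write per group wins)
#' @noRd
group_max <- function(x, g, ng) {
  o <- order(g, x)
  out <- rep(-Inf, ng)
  out[g[o]] <- x[o]
  out
}
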