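# Dataset readers and report writers.  All readers reject malformed input
# with the offending line or record named rather than silently coercing.

#' Load guide records from a guide table or FASTA file
#'
#' Guide tables are delimited text (tab or comma, sniffed from the
#' header) with columns `id`, `sequence`, and optionally `efficiency`
#' (percent, 0-100) and `structure` (dot-bracket).  FASTA files yield
#' records without labels.  Sequences are normalized (uppercase, T->U);
#' file order is preserved; duplicate ids are rejected.
#'
#' @param path Input file.
#' @param format `"guide_table"` or `"fasta"`.
#' @param ambiguity Sequence ambiguity policy, `"strict"` or
#'   `"uniform"`.
#' @return List of [guide_record()]s.
#' @export
load_dataset <- function(path, format = c("guide_table", "fasta"),
                         ambiguity = c("strict", "uniform")) {
  format <- match.arg(format)
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) gg_stop("gg_format_error", "no such file: %s", path)
  records <- if (format == "fasta") {
    read_fasta_records(path, ambiguity)
  } else {
    read_guide_table(path, ambiguity)
  }
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    gg_stop("gg_format_error", "duplicate id(s) in %s: %s", path,
            paste(dup, collapse = ", "))
  }
  records
}

#' @noRd
read_fasta_records <- function(path, ambiguity) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  lapply(seq_along(seqs), function(i) {
    guide_record(ids[i], as.character(seqs[[i]]), ambiguity = ambiguity)
  })
}

#' @noRd
read_guide_table <- function(path, ambiguity) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      colClasses = "character", comment.char = "", quote = "\""),
    error = function(e) gg_stop("gg_format_error", "malformed guide table %s: %s",
                                path, conditionMessage(e))
  )
  need <- c("id", "sequence")
  if (!all(need %in% names(df))) {
    gg_stop("gg_format_error", "guide table %s must have columns 'id' and 'sequence'", path)
  }
  lapply(seq_len(nrow(df)), function(i) {
    line_no <- i + 1L
    eff <- NA_real_
    if ("efficiency" %in% names(df) && nzchar(trimws(df$efficiency[i]))) {
      eff <- suppressWarnings(as.numeric(df$efficiency[i]))
      if (is.na(eff)) {
        gg_stop("gg_format_error", "%s line %d: non-numeric efficiency '%s'",
                path, line_no, df$efficiency[i])
      }
    }
    s <- NULL
    if ("structure" %in% names(df) && nzchar(trimws(df$structure[i]))) {
      s <- tryCatch(parse_dot_bracket(trimws(df$structure[i])),
                    guidegraph_error = function(e) {
                      gg_stop("gg_format_error", "%s line %d: %s", path, line_no,
                              conditionMessage(e))
                    })
    }
    tryCatch(
      guide_record(df$id[i], df$sequence[i], efficiency = eff, structure = s,
                   ambiguity = ambiguity),
      guidegraph_error = function(e) {
        gg_stop("gg_format_error", "%s line %d: %s", path, line_no, conditionMessage(e))
      }
    )
  })
}

#' Write guide records to a guide table
#'
#' Tab-delimited with header `id`, `sequence`, `efficiency`,
#' `structure`; absent labels/structures become empty fields.
#'
#' @param records List of [guide_record()]s.
#' @param path Output path.
#' @export
write_guide_table <- function(records, path) {
  df <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    sequence = vapply(records, `[[`, character(1), "sequence"),
    efficiency = vapply(records, function(r) {
      if (is.na(r$efficiency)) "" else format(r$efficiency, digits = 15)
    }, character(1)),
    structure = vapply(records, function(r) {
      if (is.null(r$structure)) "" else r$structure$dot_bracket
    }, character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
write_metric_report <- function(report, path) {
  df <- data.frame(metric = c("spearman", "pearson", "mse", "n"),
                   value = c(report$spearman, report$pearson, report$mse, report$n))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
write_provenance <- function(path, command, params) {
  jsonlite::write_json(
    list(package = "guidegraph",
         version = as.character(utils::packageVersion("guidegraph")),
         command = command,
         parameters = params,
         r_version = R.version.string),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
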