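#' @title Internal utilities: logging, TSV dialect, seeds
#' @name gusome-utils
#' @keywords internal
NULL

.log_env <- new.env(parent = emptyenv())
.log_env$verbose <- TRUE

#' Enable or disable stage logging
#'
#' Log messages are written to standard error with a timestamp, stage and
#' level, e.g. `[2026-01-01 12:00:00] INFO discover: 130 accepted`.
#'
#' @param verbose logical; emit messages when `TRUE`.
#' @return the previous setting, invisibly.
#' @export
gus_verbose <- function(verbose = TRUE) {
  old <- .log_env$verbose
  .log_env$verbose <- isTRUE(verbose)
  invisible(old)
}

gus_log <- function(stage, ..., level = "INFO") {
  if (!.log_env$verbose) return(invisible(NULL))
  message(sprintf("[%s] %s %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, stage, paste0(...)))
}

#' Read a tab-separated table with schema validation
#'
#' TSV dialect: tab-delimited, header row, UTF-8, no quoting, `"."` for
#' missing values. Row order is preserved.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @param numeric_cols columns (by name) validated and parsed as numeric;
#'   defaults to none. Use `TRUE` to parse every non-required remaining
#'   column as numeric (count-table layout).
#' @return a `data.frame`, row order as on disk.
#' @export
read_table <- function(path, required = character(), numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   na.strings = ".", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  if (isTRUE(numeric_cols)) numeric_cols <- setdiff(names(df), required)
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0) {
        stop("non-numeric value in column '", col, "' at row ", bad[1],
             " of ", basename(path))
      }
      df[[col]] <- parsed
    }
  }
  df
}

#' Write a table in the package TSV dialect
#'
#' Tab-delimited, no quoting, `"."` for missing, UTF-8. A comment header
#' records the coordinate convention so outputs are self-describing.
#'
#' @param df data.frame.
#' @param path output path.
#' @param header optional character vector of `# `-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  is_num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(is_num)) {
    out[[j]] <- ifelse(is.na(df[[j]]), ".",
                       format(df[[j]], trim = TRUE, digits = 15,
                              scientific = FALSE))
  }
  for (j in which(!is_num)) out[[j]] <- ifelse(is.na(df[[j]]), ".", as.character(df[[j]]))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# Derive a reproducible sub-seed for a named stage from a master seed, so
# stages can be re-run independently. Kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

# Run code under a local RNG state (does not disturb the caller's stream).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
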