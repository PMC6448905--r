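# Internal helpers shared across the pipeline.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the prior
#' RNG state, so seeded pipeline steps do not perturb the caller's random
#' stream. With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop()/validation with a consistent prefix; keeps call noise out of messages
fail <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    fail("%s: missing required column(s): %s", what,
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

read_tsv <- function(path, what, header = TRUE, col.names = NULL) {
  if (!file.exists(path)) fail("%s: file not found: %s", what, path)
  args <- list(path, sep = "\t", header = header, quote = "",
               comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character", blank.lines.skip = TRUE,
               fileEncoding = "UTF-8")
  if (!is.null(col.names)) args$col.names <- col.names
  df <- tryCatch(do.call(utils::read.delim, args),
                 error = function(e) {
                   # an empty body with a header is a legitimate empty table
                   if (grepl("no lines available", conditionMessage(e)))
                     return(NULL)
                   fail("%s: cannot parse %s (%s)", what, path,
                        conditionMessage(e))
                 })
  df
}

# Tabs and newlines inside free text are escaped in the one-row-per-record
# TSV dialect used for corpora and dyads.
escape_text <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_text <- function(x) {
  vapply(x, function(s) {
    out <- character(0)
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (length(parts) == 0L) return("")
    i <- 1L
    buf <- parts[1L]
    while (i < length(parts)) {
      i <- i + 1L
      p <- parts[i]
      if (identical(p, "")) { # escaped backslash
        buf <- paste0(buf, "\\")
        if (i < length(parts)) { i <- i + 1L; buf <- paste0(buf, parts[i]) }
      } else if (startsWith(p, "t")) {
        buf <- paste0(buf, "\t", substring(p, 2L))
      } else if (startsWith(p, "n")) {
        buf <- paste0(buf, "\n", substring(p, 2L))
      } else {
        buf <- paste0(buf, "\\", p)
      }
    }
    buf
  }, character(1), USE.NAMES = FALSE)
}

# md5 of a canonical deparse of a parameter list; used in output headers so a
# re-run with identical inputs is byte-identical while config drift is visible
config_hash <- function(params) {
  txt <- paste(deparse(params, control = "exact"), collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

# Write a data.frame as TSV under '#'-prefixed provenance header lines.
write_output_tsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wb") # binary: fixed "\n", byte-identical re-runs
  on.exit(close(con), add = TRUE)
  hdr <- c(sprintf("# metamine %s",
                   as.character(utils::packageVersion("metamine"))),
           if (!is.null(meta)) sprintf("# %s: %s", names(meta), unlist(meta)))
  writeLines(hdr, con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
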