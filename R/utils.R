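# Internal helpers: classed error conditions, locale-tolerant parsing, logging.

tc_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "toxconcord_error", "error")))
}

# Numeric parser tolerant of German-locale exports (decimal comma) and of
# instrument placeholders such as "Undetermined". Returns NA for anything
# that is not a number after normalization.
parse_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    tc_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")),
            "toxconcord_schema_error")
  }
  invisible(df)
}

# Log collector: every applied cutoff and every discarded record is recorded
# with a reason code so a pipeline run can be audited.
tc_logger <- function() {
  lines <- character(0)
  list(
    log = function(fmt, ...) {
      line <- sprintf(fmt, ...)
      lines <<- c(lines, line)
      invisible(line)
    },
    lines = function() lines
  )
}

# Run an expression with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
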