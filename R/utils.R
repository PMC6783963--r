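# internal helpers shared across modules

# Run `expr` under a local RNG state seeded with `seed`; if seed is NULL the
# global stream is used (and advanced) as usual.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_schema <- function(...) stop(sprintf(...), call. = FALSE)

# sniff the field separator of a delimited text file (comma vs semicolon);
# decimal commas (e.g. "1,23" in a semicolon file) are rejected rather than
# silently misread.
sniff_sep <- function(path) {
  head <- readLines(path, n = 2L)
  if (length(head) == 0L) stop_schema("empty file: %s", path)
  n_semi <- lengths(regmatches(head[1], gregexpr(";", head[1], fixed = TRUE)))
  n_comma <- lengths(regmatches(head[1], gregexpr(",", head[1], fixed = TRUE)))
  sep <- if (n_semi > n_comma) ";" else ","
  if (sep == ";" && length(head) > 1L &&
      grepl("(^|;)\\s*-?[0-9]+,[0-9]+\\s*(;|$)", head[2])) {
    stop_schema(
      "file %s appears to use decimal commas; convert to decimal points", path)
  }
  sep
}

read_delim_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, strip.white = TRUE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_schema("%s is missing required column(s): %s",
                what, paste(miss, collapse = ", "))
  }
  invisible(df)
}
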