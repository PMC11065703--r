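# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting and no call in the condition
stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check that `df` has all `cols`; error names the first missing column.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

# A short digest of parameter values carried on result tables for provenance.
params_digest <- function(...) {
  prm <- list(...)
  paste(names(prm), vapply(prm, function(x) paste(format(x), collapse = ","),
                           character(1)),
        sep = "=", collapse = ";")
}
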