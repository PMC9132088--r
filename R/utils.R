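# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_aaplr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "aaplr_error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_aaplr(sprintf("`%s` must be a single non-missing number", name),
                "aaplr_invalid_parameter")
  }
  if (x < min || x > max) {
    abort_aaplr(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x),
                "aaplr_invalid_parameter")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_aaplr(sprintf("`%s` must be an integer, got %s", name, x),
                "aaplr_invalid_parameter")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_aaplr(sprintf("%s is missing column(s): %s", what,
                        paste(missing, collapse = ", ")),
                "aaplr_schema_error")
  }
  invisible(df)
}

# sum that returns 0 (not NA) on empty input
sum0 <- function(x) if (length(x)) sum(x) else 0

# canonical unordered pair key for edge tables
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
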