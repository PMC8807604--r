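# Internal helpers shared across the pipeline.

# Abort with a consistent error class so callers (and the CLI) can
# distinguish user input problems from internal assertion failures.
stop_input <- function(msg, ...) {
  rlang::abort(msg, class = "csarlui_input_error", ...)
}

stop_internal <- function(msg, ...) {
  rlang::abort(msg, class = "csarlui_internal_error", ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_input(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s",
      name, x,
      if (strict_min) "(" else "[", min, max, if (strict_max) ")" else "]"
    ))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic child seed for a named random stream. Seeds derived this
# way stay below 2^31 and are stable across platforms, so adding a new
# stream never perturbs an existing one.
derive_seed <- function(master_seed, stream) {
  stopifnot(length(stream) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- as.double(master_seed %% 2147483647L)
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate an expression under a temporary RNG state seeded from a named
# stream; the caller's RNG state is restored afterwards.
with_stream <- function(master_seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master_seed, stream))
  expr
}
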