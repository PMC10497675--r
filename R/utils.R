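#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG stream without disturbing the caller's
# global RNG state. Every stochastic operation in the package takes an
# explicit integer seed and routes through here.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

stop_if_not_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
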