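#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a master seed. Kept below 2^31 - 1 so it
# is always a valid R integer seed.
substream_seed <- function(seed, stream) {
  seed <- as.numeric(seed)
  (abs(seed) + 999983 * as.numeric(stream)) %% 2147483629 + 1
}

# Run `expr` with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
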