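#' @keywords internal
"_PACKAGE"

# Run expr under a private RNG stream, restoring the caller's .Random.seed.
# All stochastic operations in the package route through this so no call
# mutates global RNG state.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Closed-open ms time axis for an epoch window [-pre, post)
epoch_time_ms <- function(pre_ms, post_ms, fs) {
  seq(-pre_ms, post_ms - 1000 / fs, by = 1000 / fs)
}
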