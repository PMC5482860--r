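#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic generators in the package
# route their randomness through this helper so that no function mutates
# global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with odd window k; edges use partial windows.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = k, FUN = mean,
                            align = "center", partial = TRUE))
}

# Centered rolling minimum, partial at the edges.
rolling_min <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = k, FUN = min,
                            align = "center", partial = TRUE))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
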