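#' @importFrom stats optim median qnorm var sd cor dist rnorm runif setNames
#' @importFrom utils head tail modifyList
#' @importFrom rlang .data
NULL

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so package functions never disturb the user's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-run child seed from a master seed, keeping the result inside
# the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483587) + 1L
}

# Linear interpolation of the first downward crossing of `level` by `v`
# after position `from` (index). Returns NA if never crossed.
first_down_crossing <- function(t, v, level, from = 1L) {
  n <- length(v)
  if (from >= n) return(NA_real_)
  idx <- seq.int(from, n - 1L)
  hit <- which(v[idx] > level & v[idx + 1L] <= level)
  if (length(hit) == 0L) return(NA_real_)
  i <- idx[hit[1L]]
  frac <- (v[i] - level) / (v[i] - v[i + 1L])
  t[i] + frac * (t[i + 1L] - t[i])
}

lin_interp <- function(t, v, t0) {
  stats::approx(t, v, xout = t0, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
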