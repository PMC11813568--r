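#' Derive a reproducible child seed from a master seed
#'
#' One master seed drives a whole simulated experiment; every participant and
#' every phase (staircase, detection) gets its own child seed so that any part
#' can be re-simulated in isolation. The split is a small multiplicative-mix
#' recurrence applied to the master seed and the stream indices; all
#' arithmetic stays exact in doubles and the result is a non-negative integer
#' below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param ... One or more integer stream indices (e.g. participant number,
#'   phase number). Order matters.
#' @return A single integer usable with [set.seed()].
#' @examples
#' split_seed(42, 3, 1)
#' @export
split_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  s <- abs(as.numeric(seed)) %% m
  for (k in as.numeric(idx)) {
    # 48271 * (m - 1) < 2^53, so the product is exact in double precision
    s <- (s * 48271 + abs(k) + 1) %% m
  }
  as.integer(s)
}

# Run an expression under a local, seeded RNG without disturbing the caller's
# RNG state. NULL seed means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
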