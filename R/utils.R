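#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft filter phyper plogis rbinom rnorm runif sd
#'   median quantile complete.cases setNames
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a private RNG stream seeded at `seed`, restoring the
# caller's RNG state afterwards. All generators route randomness through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seeds so that each stage of a multi-stage
# generation draws from an independent stream of one master seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Circular 1-based index into a vector of length n for (possibly out of
# range) 1-based positions i.
circ_index <- function(i, n) ((i - 1L) %% n) + 1L

# Sum of x[p + from .. p + to] for every position p, with circular wrap.
# x must be free of NA (mask separately).
window_sum_offset <- function(x, from, to) {
  n <- length(x)
  span <- to - from + 1L
  stopifnot(span >= 1L, span <= n)
  x3 <- c(x, x, x)
  cs <- c(0, cumsum(x3))
  p <- seq_len(n)
  cs[n + p + to + 1L] - cs[n + p + from]
}

# Centered circular running mean, odd window.
running_mean_circular <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L, window <= length(x))
  h <- (window - 1L) %/% 2L
  window_sum_offset(x, -h, h) / window
}

# Weighted sampling of `size` indices 1..n with replacement, prob ~ w.
# Inversion sampling: deterministic given RNG state and O((n+size) log n).
sample_prob_int <- function(n, size, w) {
  stopifnot(length(w) == n, all(w >= 0), any(w > 0))
  cw <- cumsum(as.numeric(w))
  u <- runif(size) * cw[n]
  findInterval(u, cw, left.open = TRUE) + 1L
}
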