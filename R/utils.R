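# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible child seed from a base seed and a string tag.
# Keeps results below 2^31 so set.seed() accepts them.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.double(seed) * 7919 + h) %% 2147483647
}

sigmoid <- function(x) stats::plogis(x)

# Centered moving average with edge shrinkage: mean of x[i-h .. i+h]
# clipped to the vector, computed in O(n) via cumulative sums.
centered_moving_average <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Trailing moving average; result has length n - w + 1 (value i covers
# elements i .. i+w-1 of x).
trailing_moving_average <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 1, w <= n)
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

# Half-open interval overlap [a0, a1) vs [b0, b1)
intervals_overlap <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1

stop_mentalstate <- function(msg, class) {
  stop(structure(
    class = c(class, "mentalstate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
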