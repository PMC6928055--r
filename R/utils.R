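# Internal helpers shared across modules.

#' Draw from a Dirichlet distribution
#'
#' Standard gamma-ratio construction: one Gamma(alpha_i, 1) draw per
#' coordinate, normalised to the simplex.
#'
#' @param n number of draws.
#' @param alpha positive concentration vector.
#' @return an `n` x `length(alpha)` matrix of simplex points.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Deterministic 31-bit hash of a string, used to derive per-sample RNG
# substreams that survive column reordering (keyed on the id, not the index).
str_seed <- function(x, base_seed) {
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% 2147483647L
  as.integer((h + as.numeric(base_seed)) %% 2147483647L)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%ifna%` <- function(x, y) ifelse(is.na(x), y, x)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}
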