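# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one parent seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Weighted empirical quantile with linear interpolation
#'
#' Computes quantiles of a weighted sample using a weighted generalisation of
#' the standard interpolation rule for equal weights (R's default type 7):
#' the i-th order statistic is placed at plotting position
#' \eqn{p_i = W_{i-1} / (S - w_{(n)})}, where \eqn{W_{i-1}} is the total
#' weight of the strictly preceding order statistics, \eqn{S} the total
#' weight and \eqn{w_{(n)}} the weight of the largest observation; quantiles
#' are linear interpolations between adjacent positions. With equal weights
#' this reduces exactly to \code{quantile(type = 7)}; \code{q = 0} and
#' \code{q = 1} always return the sample minimum and maximum.
#'
#' @param v numeric sample values.
#' @param w positive weights, same length as `v` (need not sum to 1).
#' @param q quantile probabilities in \[0, 1\] (vectorised).
#' @return numeric vector of quantiles, one per element of `q`.
#' @export
weighted_quantile <- function(v, w, q) {
  if (length(v) != length(w)) stop("`v` and `w` must have equal length")
  if (length(v) == 0L) stop("empty sample")
  if (any(!is.finite(v)) || any(!is.finite(w)) || any(w <= 0)) {
    stop("values must be finite and weights strictly positive")
  }
  if (any(q < 0 | q > 1)) stop("quantile probabilities must lie in [0, 1]")
  if (length(v) == 1L) return(rep(v, length(q)))
  o <- order(v)
  v <- v[o]
  w <- w[o]
  s <- sum(w)
  p <- cumsum(c(0, w[-length(w)])) / (s - w[length(w)])
  stats::approx(p, v, xout = q, method = "linear", rule = 2,
                ties = "ordered")$y
}
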