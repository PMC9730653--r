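#' Percentile bootstrap confidence interval for the mean
#'
#' Resamples the data with replacement `B` times, computes the mean of
#' each resample, and returns the percentile interval of the resample
#' means at the requested level (type-7 quantiles). Deterministic given
#' the seed. A single observation yields the degenerate interval
#' `[v, v]` with a warning.
#'
#' @param values numeric vector.
#' @param level confidence level (default 0.95).
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @return named numeric `c(lo, hi)` with attribute `level`.
#' @export
bootstrap_ci <- function(values, level = 0.95, B = 10000L, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no finite values")
  if (n == 1) {
    cpw_warn("bootstrap CI of a single value is degenerate")
    return(structure(c(lo = values, hi = values), level = level))
  }
  stopifnot(B >= 1, level > 0, level < 1)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n, ncol = B))
  })
  alpha <- (1 - level) / 2
  q <- quantile(means, c(alpha, 1 - alpha), type = 7, names = FALSE)
  structure(c(lo = q[1], hi = q[2]), level = level)
}
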