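#' @importFrom stats median quantile rnorm rpois rnbinom rlnorm runif sd
#'   setNames complete.cases loess predict qt p.adjust phyper prcomp
#'   aggregate
#' @importFrom utils read.delim write.csv read.csv head modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. All stochastic operations in the
# package funnel through this so that a single integer seed makes a
# whole run reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream-specific child seed from a master seed. Keeps results
# below .Machine$integer.max and decorrelates streams by a large odd
# multiplier.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483399) + 1L
}

cpw_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

cpw_warn <- function(...) cpw_log(..., level = "WARN")

`%||%` <- function(a, b) if (is.null(a)) b else a

# type-7 quartile summary with 1.5*IQR whiskers (whiskers clipped to the
# most extreme data point inside the fences)
five_num <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  c(
    whisker_lo = min(x[x >= lo_fence]),
    q1 = q[1], median = q[2], q3 = q[3],
    whisker_hi = max(x[x <= hi_fence])
  )
}
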