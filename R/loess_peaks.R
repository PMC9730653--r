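#' Loess temporal summary with t-based band
#'
#' Locally-weighted linear regression (tricube weights, degree 1) of
#' values on time via [stats::loess()], evaluated on a grid spanning
#' the observed times, with a pointwise band `fit +/- t(df) * SE` where
#' the degrees of freedom come from the smoother's trace approximation
#' (the `one.delta` correction reported by loess).
#'
#' @param times,values numeric vectors; at least 4 distinct times.
#' @param span loess span (fraction of points per neighborhood).
#' @param grid evaluation grid (default: 80 points across the observed
#'   time range).
#' @param level band level.
#' @param log_time fit on `log2(time)`; natural for geometric sampling
#'   designs (2, 12, 24, 48, 96 h). Requires positive times.
#' @return data.frame (time, fit, se, lo, hi) of class `loess_curve`
#'   with the model in attribute `model`.
#' @export
loess_fit <- function(times, values, span = 0.5, grid = NULL,
                      level = 0.95, log_time = FALSE) {
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (length(unique(times)) < 4)
    stop("loess_fit needs >= 4 distinct time values")
  if (log_time && any(times <= 0))
    stop("log_time = TRUE requires positive times")
  if (is.null(grid))
    grid <- seq(min(times), max(times), length.out = 80)
  x <- if (log_time) log2(times) else times
  gx <- if (log_time) log2(grid) else grid

  n_local <- ceiling(span * length(x))
  if (n_local < 3)
    stop("span too small: local fits need >= 3 points; use span >= ",
         signif(3 / length(x), 2))
  fit <- tryCatch(
    loess(values ~ x, span = span, degree = 1,
          family = "gaussian",
          control = stats::loess.control(surface = "direct")),
    error = function(e) stop("loess failed (span ", span, "): ",
                             conditionMessage(e)))
  pr <- predict(fit, data.frame(x = gx), se = TRUE)
  tq <- qt(1 - (1 - level) / 2, pr$df)
  out <- data.frame(time = grid, fit = pr$fit, se = pr$se.fit,
                    lo = pr$fit - tq * pr$se.fit,
                    hi = pr$fit + tq * pr$se.fit)
  structure(out, class = c("loess_curve", "data.frame"), model = fit,
            log_time = log_time, level = level)
}

#' Peak time of a temporal summary
#'
#' The observed time point closest to the argmax of the loess curve
#' (ties resolved toward the earlier time). Local maxima of the
#' per-time point estimates are reported alongside (a point is a local
#' maximum when it exceeds its grid neighbors; an endpoint qualifies
#' when it exceeds its single neighbor). A curve whose range is below
#' `tolerance` has no peak.
#'
#' @param timecourse a `time_course` object (see [time_course()]), or a
#'   list with `times` (observed time points), `estimates` (per-time
#'   point estimates) and `curve` (a [loess_fit()] result).
#' @param tolerance flatness tolerance on the loess fit range.
#' @return list with `peak_time_h` (or `NA` for a flat curve),
#'   `local_maxima_h` (times of discrete local maxima) and `flat`.
#' @export
peak_time <- function(timecourse, tolerance = 1e-8) {
  curve <- timecourse$curve
  if (is.null(curve)) stop("loess fit unavailable")
  rng <- diff(range(curve$fit))
  if (!is.finite(rng) || rng < tolerance) {
    return(list(peak_time_h = NA_real_, local_maxima_h = numeric(0),
                flat = TRUE))
  }
  t_star <- curve$time[which.max(curve$fit)]
  obs <- sort(unique(timecourse$times))
  d <- abs(obs - t_star)
  peak <- obs[which(d == min(d))][1]  # earlier time wins ties

  est <- timecourse$estimates[match(obs, timecourse$times)]
  is_max <- vapply(seq_along(obs), function(i) {
    left <- if (i > 1) est[i] > est[i - 1] else TRUE
    right <- if (i < length(obs)) est[i] > est[i + 1] else TRUE
    left && right
  }, logical(1))
  list(peak_time_h = peak, local_maxima_h = obs[is_max], flat = FALSE)
}

#' Per-time summary of a measured quantity
#'
#' Builds the standard temporal summary used throughout the package:
#' per time point the mean of the supplied values, a percentile
#' bootstrap confidence interval, and a loess curve over the times with
#' its peak call.
#'
#' @param times per-observation time in hours.
#' @param values per-observation measurements (animal- or spot-level).
#' @param level CI and band level.
#' @param B bootstrap resamples.
#' @param span loess span.
#' @param seed seed for the bootstrap.
#' @param log_time passed to [loess_fit()].
#' @param min_n time points with fewer observations are flagged
#'   unreliable.
#' @param fit_curve fit the loess curve (callers that smooth a derived
#'   summary instead, e.g. per-time medians, turn this off).
#' @return object of class `time_course`: list with `summary`
#'   (data.frame: time_h, n, estimate, median, lo, hi, reliable),
#'   `times`, `estimates`, `curve`, `peak`.
#' @export
time_course <- function(times, values, level = 0.95, B = 10000L,
                        span = 0.5, seed = 1L, log_time = TRUE,
                        min_n = 3L, fit_curve = TRUE) {
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  tps <- sort(unique(times))
  rows <- lapply(seq_along(tps), function(i) {
    v <- values[times == tps[i]]
    ci <- if (length(v) >= 2) {
      bootstrap_ci(v, level, B, seed = child_seed(seed, i))
    } else c(lo = v, hi = v)
    data.frame(time_h = tps[i], n = length(v), estimate = mean(v),
               median = median(v), lo = ci[["lo"]], hi = ci[["hi"]],
               reliable = length(v) >= min_n)
  })
  summ <- do.call(rbind, rows)
  curve <- if (fit_curve && length(tps) >= 4) {
    loess_fit(times, values, span = span, level = level,
              log_time = log_time && all(tps > 0))
  }
  tc <- structure(
    list(summary = summ, times = summ$time_h, estimates = summ$estimate,
         curve = curve, level = level),
    class = "time_course")
  tc$peak <- if (!is.null(curve)) peak_time(tc)
  tc
}

#' @export
print.time_course <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$peak) && !x$peak$flat)
    cat("peak at", x$peak$peak_time_h, "h; local maxima:",
        paste(x$peak$local_maxima_h, collapse = ", "), "h\n")
  invisible(x)
}
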