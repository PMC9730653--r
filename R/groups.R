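#' Group summary (animal-level boxplot statistics)
#'
#' Median, quartiles (type-7 linear interpolation) and whiskers
#' extending to the most extreme values within 1.5 interquartile
#' ranges of the box, per group of animal-level means.
#'
#' @param values numeric vector of animal-level values.
#' @param group group label.
#' @return one-row data.frame (group, n, whisker_lo, q1, median, q3,
#'   whisker_hi, mean).
#' @export
group_summary <- function(values, group = "group") {
  fn <- five_num(values)
  data.frame(group = group, n = sum(is.finite(values)),
             whisker_lo = fn[["whisker_lo"]], q1 = fn[["q1"]],
             median = fn[["median"]], q3 = fn[["q3"]],
             whisker_hi = fn[["whisker_hi"]],
             mean = mean(values[is.finite(values)]),
             stringsAsFactors = FALSE)
}

#' Compare condition groups (knockout series)
#'
#' Summarises each group of animal-level means and runs two-sided exact
#' rank-sum tests for the requested pairs, BH-adjusted over the
#' comparison family. Groups below `min_n` animals are summarised but
#' excluded from testing (with a warning).
#'
#' @param values named list: group name -> numeric vector of
#'   animal-level means (sections averaged within animal first).
#' @param pairs list of length-2 character vectors naming the
#'   comparisons; default: all pairs.
#' @param min_n minimum group size for testing.
#' @return list with `summary` (data.frame of [group_summary()] rows)
#'   and `tests` (data.frame: group1, group2, statistic, p, p_adj).
#' @export
group_compare <- function(values, pairs = NULL, min_n = 3L) {
  stopifnot(is.list(values), !is.null(names(values)))
  summ <- do.call(rbind, lapply(names(values), function(g) {
    group_summary(values[[g]], g)
  }))
  testable <- names(values)[vapply(values, length, integer(1)) >= min_n]
  small <- setdiff(names(values), testable)
  if (length(small) > 0)
    cpw_warn("group(s) below n = ", min_n, " excluded from testing: ",
             paste(small, collapse = ", "))
  if (is.null(pairs)) {
    pairs <- if (length(testable) >= 2) {
      cmb <- utils::combn(testable, 2)
      lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    } else list()
  }
  pairs <- Filter(function(p) all(p %in% testable), pairs)
  tests <- NULL
  if (length(pairs) > 0) {
    tests <- do.call(rbind, lapply(pairs, function(p) {
      t <- ranksum_test(values[[p[1]]], values[[p[2]]])
      data.frame(group1 = p[1], group2 = p[2], statistic = t$statistic,
                 p = t$p_value, stringsAsFactors = FALSE)
    }))
    tests$p_adj <- bh_adjust(tests$p)
  }
  list(summary = summ, tests = tests)
}
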