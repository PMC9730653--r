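#' Gene-set score time course per region
#'
#' Scores every spot with [score_gene_set()], then summarises the
#' score distribution per (region, time point) with the median and a
#' percentile bootstrap CI, fits a loess curve through the per-time
#' score medians of the requested region and calls the peak time. Cells with fewer than `min_spots` spots are flagged
#' unreliable.
#'
#' @param norm a `normalized_expr` or genes x spots matrix.
#' @param set gene symbols to score.
#' @param regions per-spot region labels.
#' @param times per-spot time in hours (0 = control; excluded from the
#'   loess fit and peak call).
#' @param region region of interest.
#' @param n_bins,n_ctrl,seed scoring parameters.
#' @param level,B,span time-course parameters.
#' @param min_spots reliability threshold per cell.
#' @param set_name label for messages.
#' @return a `time_course` (see [time_course()]) with the per-spot
#'   scores of the region in `$scores`.
#' @export
gene_set_time_course <- function(norm, set, regions, times, region,
                                 n_bins = 25L, n_ctrl = 50L, seed = 1L,
                                 level = 0.95, B = 10000L, span = 0.5,
                                 min_spots = 3L,
                                 set_name = "gene set") {
  sc <- score_gene_set(norm, set, n_bins, n_ctrl, seed, set_name)
  keep <- regions == region & times > 0
  tc <- time_course(times[keep], sc[keep], level = level, B = B,
                    span = span, seed = child_seed(seed, 777L),
                    log_time = TRUE, min_n = min_spots,
                    fit_curve = FALSE)
  # the curve smooths the per-time medians, not the replicated
  # per-spot scores (whose replication breaks the span fraction)
  if (nrow(tc$summary) >= 4) {
    tc$estimates <- tc$summary$median
    # at least 4 points per neighborhood: with 3, the symmetric outer
    # points get zero tricube weight and the local fit is singular
    tc$curve <- loess_fit(tc$summary$time_h, tc$summary$median,
                          span = max(span, 4 / nrow(tc$summary) + 1e-9),
                          level = level, log_time = TRUE)
    tc$peak <- peak_time(tc)
  }
  tc$scores <- data.frame(time_h = times[keep], score = sc[keep])
  tc$region <- region
  tc
}
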