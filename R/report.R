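utils::globalVariables(c("time_h", "estimate", "lo", "hi", "fit",
                         "time", "group", "median", "q1", "q3",
                         "whisker_lo", "whisker_hi", "mean_intensity"))

write_tc_csv <- function(tc, path) {
  write.csv(tc$summary, path, row.names = FALSE)
  if (!is.null(tc$curve))
    write.csv(as.data.frame(tc$curve),
              sub("\\.csv$", "_loess.csv", path), row.names = FALSE)
  invisible(path)
}

plot_time_course <- function(tc, ylab, title) {
  p <- ggplot2::ggplot(tc$summary, ggplot2::aes(time_h, estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi),
                           width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = tc$summary$time_h) +
    ggplot2::labs(x = "time after injection (h)", y = ylab,
                  title = title) +
    ggplot2::theme_bw()
  if (!is.null(tc$curve)) {
    p <- p + ggplot2::geom_line(
      data = as.data.frame(tc$curve), ggplot2::aes(time, fit),
      color = "steelblue")
  }
  p
}

plot_groups <- function(gc, ylab, title) {
  ggplot2::ggplot(gc$summary, ggplot2::aes(x = group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = whisker_lo, lower = q1, middle = median,
                   upper = q3, ymax = whisker_hi),
      stat = "identity", width = 0.6) +
    ggplot2::labs(x = NULL, y = ylab, title = title) +
    ggplot2::theme_bw()
}

save_figure <- function(plot, path, width = 5, height = 4) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Assemble the analysis report
#'
#' Writes every available result to `outdir`: time-course plots with
#' bootstrap-CI error bars and the loess line, knockout boxplots,
#' marker tables, enrichment tables, average-intensity map TIFFs —
#' each figure backed by a CSV — plus a `manifest.txt` (flat
#' key-value) listing parameters, seeds and any skipped sections.
#' Missing upstream results are skipped, not errors.
#'
#' @param results named list; recognised elements: `assignment_table`
#'   (data.frame), `dge`, `top_k`, `enrichment` (data.frames),
#'   `score_tc`, `leakage_tc`, `cd45_tc`, `icam1_tc` (`time_course`
#'   objects), `knockout` (named list of [group_compare()] outputs),
#'   `maps` (named list of `intensity_map`s).
#' @param outdir output directory.
#' @param config a [run_config()] recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
build_report <- function(results, outdir, config = run_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  skipped <- character(0)
  done <- character(0)
  emit <- function(name, fn) {
    if (is.null(results[[name]])) {
      skipped <<- c(skipped, name)
    } else {
      fn(results[[name]])
      done <<- c(done, name)
    }
  }

  emit("assignment_table", function(x)
    write.csv(x, file.path(outdir, "region_assignment.csv"),
              row.names = FALSE))
  emit("dge", function(x)
    write.csv(x, file.path(outdir, "dge.csv"), row.names = FALSE))
  emit("top_k", function(x)
    write.csv(x, file.path(outdir, "top_markers.csv"),
              row.names = FALSE))
  emit("enrichment", function(x)
    write.csv(x, file.path(outdir, "enrichment.csv"),
              row.names = FALSE))
  emit("score_tc", function(tc) {
    write_tc_csv(tc, file.path(outdir, "score_timecourse.csv"))
    save_figure(plot_time_course(tc, "gene-set score",
                                 "Pathway score time course"),
                file.path(outdir, "score_timecourse.png"))
  })
  for (nm in c("leakage_tc", "cd45_tc", "icam1_tc")) {
    local({
      n <- nm
      emit(n, function(tc) {
        write_tc_csv(tc, file.path(outdir, paste0(n, ".csv")))
        save_figure(plot_time_course(tc, "value", n),
                    file.path(outdir, paste0(n, ".png")))
      })
    })
  }
  emit("knockout", function(kns) {
    for (nm in names(kns)) {
      write.csv(kns[[nm]]$summary,
                file.path(outdir, paste0("knockout_", nm, "_summary.csv")),
                row.names = FALSE)
      if (!is.null(kns[[nm]]$tests))
        write.csv(kns[[nm]]$tests,
                  file.path(outdir, paste0("knockout_", nm, "_tests.csv")),
                  row.names = FALSE)
      save_figure(plot_groups(kns[[nm]], "normalized intensity",
                              paste("Knockout series:", nm)),
                  file.path(outdir, paste0("knockout_", nm, ".png")))
    }
  })
  emit("maps", function(maps) {
    for (nm in names(maps))
      write_intensity_map(maps[[nm]],
                          file.path(outdir, paste0("map_", nm, ".tiff")))
  })

  manifest <- c(
    sprintf("package_version=%s",
            as.character(utils::packageVersion("cpwave"))),
    sprintf("generated=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    vapply(names(unclass(config)), function(k) {
      sprintf("config.%s=%s", k,
              paste(unlist(config[[k]]), collapse = ","))
    }, character(1)),
    sprintf("sections_written=%s", paste(done, collapse = ",")),
    sprintf("sections_skipped=%s", paste(skipped, collapse = ","))
  )
  manifest_path <- file.path(outdir, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(manifest_path)
}
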