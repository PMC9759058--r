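#' Static plots of the per-experiment and comparison analytics
#'
#' `plotTimeline()` draws the alveolar-area timeline with each cycle's
#' min/max band; `plotCycleOverlay()` overlays the per-cycle traces on a
#' common phase axis; `plotSummaryRadar()` draws the normalized Kiviat
#' (radar) summary of one or more experiments; `plotSlopeChart()` and
#' `plotCycleDifferences()` are the two-experiment charts. All return
#' ggplot objects; save with [ggplot2::ggsave()].
#'
#' @param series per-frame statistics data.frame.
#' @param cycles data.frame from [detectCycles()] (may be `NULL`).
#' @param overlay data.frame from [cycleOverlay()].
#' @param summaries named list of [summarizeExperiment()] vectors.
#' @param comparison list from [compareExperiments()].
#' @param feature per-frame feature column name.
#' @return a ggplot object.
#' @name pipeline-plots
NULL

#' @rdname pipeline-plots
#' @export
plotTimeline <- function(series, cycles = NULL) {
  p <- ggplot2::ggplot(series,
         ggplot2::aes(x = .data$frame_index, y = .data$alveolar_area_pct)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "frame", y = "alveolar area (% of image)")
  if (!is.null(cycles) && nrow(cycles) > 0L)
    p <- p + ggplot2::geom_rect(
      data = cycles, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_frame, xmax = .data$end_frame,
                   ymin = .data$min_alveolar_pct,
                   ymax = .data$max_alveolar_pct),
      alpha = 0.15, fill = "grey40", color = "grey60", linewidth = 0.2)
  p
}

#' @rdname pipeline-plots
#' @export
plotCycleOverlay <- function(overlay) {
  ggplot2::ggplot(overlay,
      ggplot2::aes(x = .data$phase, y = .data$alveolar_area_pct,
                   group = .data$cycle_index,
                   color = factor(.data$cycle_index))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frames since cycle start",
                  y = "alveolar area (% of image)", color = "cycle")
}

#' @rdname pipeline-plots
#' @export
plotSummaryRadar <- function(summaries) {
  norm <- normalizeSummaries(summaries)
  df <- do.call(rbind, lapply(seq_len(nrow(norm)), function(i)
    data.frame(experiment = if (!is.null(names(summaries)))
                 names(summaries)[i] else paste0("exp", i),
               axis = colnames(norm), value = norm[i, ])))
  # close the polygon
  df <- rbind(df, df[df$axis == colnames(norm)[1L], ])
  df$axis <- factor(df$axis, levels = colnames(norm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$value,
                                   group = .data$experiment,
                                   color = .data$experiment)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.7) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname pipeline-plots
#' @export
plotSlopeChart <- function(comparison, feature) {
  p <- comparison$slope_pairs[[.checkFeature(feature)]]
  df <- data.frame(
    experiment = rep(c("A", "B"), each = 2L),
    end = rep(c("start", "end"), 2L),
    value = c(p$A[["start_value"]], p$A[["end_value"]],
              p$B[["start_value"]], p$B[["end_value"]]))
  df$end <- factor(df$end, levels = c("start", "end"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$end, y = .data$value,
                                   group = .data$experiment,
                                   color = .data$experiment)) +
    ggplot2::geom_line(linewidth = 0.8) + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = feature)
}

#' @rdname pipeline-plots
#' @export
plotCycleDifferences <- function(comparison, feature) {
  d <- comparison$cycle_differences[[.checkFeature(feature)]]
  df <- data.frame(cycle = seq_along(d) - 1L, difference = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$difference)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::labs(x = "aligned cycle", y = paste0("|A - B| ", feature))
}

#' @importFrom ggplot2 .data
NULL
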