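.COMPARISON_FEATURES <- c("alveolar_area_pct", "alveoli_count",
                          "airspace_per_alveolus_pct", "neutrophil_count",
                          "neutrophil_area_pct", "interstitial_area_pct")

.checkFeature <- function(feature) {
  if (length(feature) != 1L || !feature %in% .COMPARISON_FEATURES)
    stop("unknown feature name: ", paste(feature, collapse = ", "))
  feature
}

#' Shift a frame-statistics series by a manual frame offset
#'
#' Used to synchronize the respiratory cycles of two experiments before
#' comparison. A positive offset drops that many leading frames, a negative
#' offset drops trailing frames; no resampling is performed and the
#' remaining frames are re-based to index 0.
#'
#' @param series data.frame of per-frame statistics.
#' @param offsetFrames signed integer, `|offset|` < number of frames.
#' @return the shifted data.frame.
#' @export
applyOffset <- function(series, offsetFrames) {
  n <- nrow(series)
  if (abs(offsetFrames) >= n)
    stop("offset of ", offsetFrames, " frames exceeds the ", n, "-frame series")
  out <- if (offsetFrames > 0) series[(offsetFrames + 1L):n, , drop = FALSE]
  else if (offsetFrames < 0) series[seq_len(n + offsetFrames), , drop = FALSE]
  else series
  out$frame_index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

#' Start-to-end change of a feature across the recording
#'
#' The slope-chart endpoints: the mean of the feature over the first
#' complete respiratory cycle and over the last one.
#'
#' @param series data.frame of per-frame statistics.
#' @param cycles data.frame from [detectCycles()] with at least one row.
#' @param feature one of the per-frame feature column names.
#' @return named numeric `c(start_value, end_value)`.
#' @export
slopeChart <- function(series, cycles, feature) {
  .checkFeature(feature)
  if (is.null(cycles) || nrow(cycles) == 0L)
    stop("slope chart requires at least one complete cycle")
  cycleMean <- function(j) {
    sel <- series$frame_index >= cycles$start_frame[j] &
      series$frame_index < cycles$end_frame[j]
    mean(series[[feature]][sel])
  }
  c(start_value = cycleMean(1L), end_value = cycleMean(nrow(cycles)))
}

#' Distribution summary of a per-frame feature
#'
#' Five-number summary plus mean of the per-frame values; quantiles use
#' linear interpolation. The raw values are attached so a plotting layer
#' can draw violins.
#'
#' @param series non-empty data.frame of per-frame statistics.
#' @param feature one of the per-frame feature column names.
#' @return named numeric `c(min, q25, median, q75, max, mean)` with the raw
#'   per-frame values in attribute `"values"`.
#' @examples
#' s <- data.frame(frame_index = 0:3, alveolar_area_pct = c(0, 0, 0, 10))
#' distributionSummary(s, "alveolar_area_pct")[["q75"]]  # 2.5
#' @export
distributionSummary <- function(series, feature) {
  .checkFeature(feature)
  if (is.null(series) || nrow(series) == 0L)
    stop("cannot summarize an empty series")
  v <- series[[feature]]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7L)
  out <- c(min = min(v), q25 = q[1L], median = q[2L], q75 = q[3L],
           max = max(v), mean = mean(v))
  attr(out, "values") <- v
  out
}

# per-cycle mean of a feature
.cycleMeans <- function(series, cycles, feature) {
  vapply(seq_len(nrow(cycles)), function(j) {
    sel <- series$frame_index >= cycles$start_frame[j] &
      series$frame_index < cycles$end_frame[j]
    mean(series[[feature]][sel])
  }, numeric(1))
}

#' Per-cycle absolute differences between two experiments
#'
#' For each aligned cycle index k, the absolute difference between the
#' per-cycle means of the feature in the two experiments:
#' `|mean_A(k) - mean_B(k)|`, for k up to the smaller cycle count.
#' Symmetric in its two series.
#'
#' @param seriesA,seriesB per-frame statistics of the two experiments
#'   (offset-aligned, see [applyOffset()]).
#' @param cyclesA,cyclesB their detected cycles.
#' @param feature one of the per-frame feature column names.
#' @return numeric vector of length `min(nrow(cyclesA), nrow(cyclesB))`.
#' @export
cycleDifferenceChart <- function(seriesA, cyclesA, seriesB, cyclesB, feature) {
  .checkFeature(feature)
  k <- min(nrow(cyclesA), nrow(cyclesB))
  if (k == 0L) return(numeric())
  abs(.cycleMeans(seriesA, cyclesA[seq_len(k), , drop = FALSE], feature) -
      .cycleMeans(seriesB, cyclesB[seq_len(k), , drop = FALSE], feature))
}

#' Full two-experiment comparison
#'
#' Applies the manual frame offset to experiment B, re-detects its cycles,
#' and computes for every per-frame feature the slope-chart endpoints, the
#' distribution summaries and the per-cycle absolute differences.
#'
#' @param seriesA,seriesB per-frame statistics of the two experiments.
#' @param offsetFrames signed frame offset applied to B (default 0).
#' @param smoothingWindow,minCycleLen,prominence cycle-detection settings,
#'   see [detectCycles()].
#' @return list with `offset_frames`, `slope_pairs` (per feature, per
#'   experiment start/end), `distribution_summaries`, `cycle_differences`,
#'   and the aligned inputs (`series_a`, `series_b`, `cycles_a`,
#'   `cycles_b`).
#' @export
compareExperiments <- function(seriesA, seriesB, offsetFrames = 0L,
                               smoothingWindow = 3L, minCycleLen = 4L,
                               prominence = 0.5) {
  seriesB <- applyOffset(seriesB, offsetFrames)
  cyclesA <- detectCycles(seriesA, smoothingWindow, minCycleLen, prominence)
  cyclesB <- detectCycles(seriesB, smoothingWindow, minCycleLen, prominence)
  slope <- lapply(.COMPARISON_FEATURES, function(f)
    list(A = slopeChart(seriesA, cyclesA, f),
         B = slopeChart(seriesB, cyclesB, f)))
  dist <- lapply(.COMPARISON_FEATURES, function(f)
    list(A = distributionSummary(seriesA, f),
         B = distributionSummary(seriesB, f)))
  diffs <- lapply(.COMPARISON_FEATURES, function(f)
    cycleDifferenceChart(seriesA, cyclesA, seriesB, cyclesB, f))
  names(slope) <- names(dist) <- names(diffs) <- .COMPARISON_FEATURES
  list(offset_frames = as.integer(offsetFrames), slope_pairs = slope,
       distribution_summaries = dist, cycle_differences = diffs,
       series_a = seriesA, series_b = seriesB,
       cycles_a = cyclesA, cycles_b = cyclesB)
}

#' Serialize a comparison result as one JSON document
#'
#' @param comparison list from [compareExperiments()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeComparisonJSON <- function(comparison, path) {
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  doc <- list(
    offset_frames = comparison$offset_frames,
    slope_pairs = lapply(comparison$slope_pairs, function(p)
      list(A = as.list(p$A), B = as.list(p$B))),
    distribution_summaries = lapply(comparison$distribution_summaries,
      function(p) list(A = as.list(strip(p$A)), B = as.list(strip(p$B)))),
    cycle_differences = comparison$cycle_differences)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Suggest a frame offset by cross-correlating alveolar-area signals
#'
#' An optional automation aid for the manual offset control: returns the
#' lag (applied to series B, see [applyOffset()]) that maximizes the
#' Pearson correlation of the two mean-centered alveolar-area signals over
#' their overlap. The manual offset remains authoritative; this is an
#' extension beyond the core comparison workflow.
#'
#' @param seriesA,seriesB per-frame statistics of the two experiments.
#' @param maxLag largest |offset| searched, frames.
#' @return the suggested signed offset (ties broken toward 0).
#' @export
suggestOffset <- function(seriesA, seriesB, maxLag = 16L) {
  a <- seriesA$alveolar_area_pct
  b <- seriesB$alveolar_area_pct
  lags <- seq.int(-maxLag, maxLag)
  score <- vapply(lags, function(l) {
    bb <- if (l > 0) b[-seq_len(l)] else b
    aa <- if (l < 0) a[-seq_len(-l)] else a
    n <- min(length(aa), length(bb))
    if (n < 4L) return(-Inf)
    suppressWarnings(stats::cor(aa[seq_len(n)], bb[seq_len(n)]))
  }, numeric(1))
  score[is.na(score)] <- -Inf
  best <- which(score >= max(score) - 1e-9) # periodic signals tie at many lags
  lags[best[which.min(abs(lags[best]))]]
}
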