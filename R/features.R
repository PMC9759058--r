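#' Per-frame scalar feature statistics
#'
#' Areas are expressed as percentages of the whole image. The airspace per
#' alveolus is the alveolar area percentage divided by the number of
#' detected alveoli in that frame (0 when none). Interstitial area is the
#' foreground fraction of a bright-polarity mask of the interstitial
#' channel.
#'
#' @param alveoli list of alveolar contours of one frame.
#' @param neutrophils list of neutrophil contours of the same frame.
#' @param interstitialMask 0/1 matrix of the bright interstitial mask, or
#'   `NULL` to report 0.
#' @param dims frame geometry `c(height, width)` in px.
#' @param frameIndex 0-based frame index recorded in the row.
#' @return one-row data.frame with columns frame_index, alveolar_area_pct,
#'   alveoli_count, airspace_per_alveolus_pct, neutrophil_count,
#'   neutrophil_area_pct, interstitial_area_pct.
#' @examples
#' ct <- list(polygon = cbind(x = 0, y = 0), area = 1000,
#'            centroid = c(x = 5, y = 5), role = "interstitial",
#'            frame_index = 0L)
#' computeFrameStats(list(ct), list(), NULL, c(100, 100))$alveolar_area_pct  # 10
#' @export
computeFrameStats <- function(alveoli, neutrophils, interstitialMask, dims,
                              frameIndex = 0L) {
  if (length(dims) != 2L || any(dims <= 0)) stop("invalid frame dimensions")
  npx <- dims[1L] * dims[2L]
  aArea <- sum(vapply(alveoli, `[[`, numeric(1), "area"))
  nArea <- sum(vapply(neutrophils, `[[`, numeric(1), "area"))
  aPct <- 100 * aArea / npx
  nct <- length(alveoli)
  data.frame(
    frame_index = as.integer(frameIndex),
    alveolar_area_pct = aPct,
    alveoli_count = nct,
    airspace_per_alveolus_pct = if (nct > 0L) aPct / nct else 0,
    neutrophil_count = length(neutrophils),
    neutrophil_area_pct = 100 * nArea / npx,
    interstitial_area_pct =
      if (is.null(interstitialMask)) 0 else 100 * sum(interstitialMask) / npx)
}

# centered moving average with shrinking windows at the edges
.movingAverage <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# local minima of x (plateau-aware: the central index of a flat bottom)
.localMinima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i < n) {
    if (x[i] < x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] > x[i]) out <- c(out, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence of a minimum: the smaller of the highest values
# reached before descending below it on either side (array edges count as
# walls)
.troughProminence <- function(x, idx) {
  vapply(idx, function(i) {
    v <- x[i]
    left <- if (i > 1L) {
      lower <- which(x[seq_len(i - 1L)] < v)
      from <- if (length(lower)) max(lower) + 1L else 1L
      max(x[from:(i - 1L)])
    } else v
    right <- if (i < length(x)) {
      after <- x[(i + 1L):length(x)]
      lower <- which(after < v)
      to <- if (length(lower)) min(lower) - 1L else length(after)
      if (to >= 1L) max(after[seq_len(to)]) else v
    } else v
    min(left, right) - v
  }, numeric(1))
}

#' Segment the alveolar-area signal into respiratory cycles
#'
#' The alveolar area percentage is smoothed by a centered moving average;
#' troughs (end-expiration) are local minima with at least the stated
#' topographic prominence and pairwise separation of `minCycleLen` frames.
#' Cycle k spans `[trough_k, trough_{k+1})`; its min/max alveolar area are
#' taken from the unsmoothed signal within the span. Frames before the
#' first and after the last trough belong to no cycle.
#'
#' @param series data.frame of per-frame statistics with columns
#'   `frame_index` and `alveolar_area_pct`.
#' @param smoothingWindow centered moving-average width, frames.
#' @param minCycleLen minimum trough separation, frames.
#' @param prominence minimum trough prominence, percentage points.
#' @return data.frame with columns cycle_index, start_frame (inclusive),
#'   end_frame (exclusive), min_alveolar_pct, max_alveolar_pct; consecutive
#'   cycles tile the covered range.
#' @examples
#' s <- data.frame(frame_index = 0:63,
#'                 alveolar_area_pct = 10 + 5 * sin(2 * pi * (0:63) / 16))
#' detectCycles(s)  # 3 cycles of 16 frames
#' @export
detectCycles <- function(series, smoothingWindow = 3L, minCycleLen = 4L,
                         prominence = 0.5) {
  stopifnot(is.data.frame(series), "alveolar_area_pct" %in% names(series))
  x <- series$alveolar_area_pct
  if (length(x) < 2L * minCycleLen)
    stop("series too short: need at least ", 2L * minCycleLen, " frames")
  sm <- .movingAverage(x, smoothingWindow)
  cand <- .localMinima(sm)
  cand <- cand[.troughProminence(sm, cand) >= prominence]
  # enforce separation: deepest troughs win
  cand <- cand[order(sm[cand])]
  troughs <- integer()
  for (i in cand)
    if (all(abs(troughs - i) >= minCycleLen)) troughs <- c(troughs, i)
  troughs <- sort(troughs)
  if (length(troughs) < 2L)
    stop("no complete respiratory cycle detected")
  fi <- series$frame_index
  k <- length(troughs) - 1L
  data.frame(
    cycle_index = seq_len(k) - 1L,
    start_frame = fi[troughs[-length(troughs)]],
    end_frame = fi[troughs[-1L]],
    min_alveolar_pct = vapply(seq_len(k), function(j)
      min(x[troughs[j]:(troughs[j + 1L] - 1L)]), numeric(1)),
    max_alveolar_pct = vapply(seq_len(k), function(j)
      max(x[troughs[j]:(troughs[j + 1L] - 1L)]), numeric(1)))
}

#' Re-index the alveolar-area trace per respiratory cycle
#'
#' Gives each cycle's alveolar-area trace relative to its start frame, for
#' overlaying cycles on a common phase axis.
#'
#' @param series data.frame of per-frame statistics.
#' @param cycles data.frame from [detectCycles()] on this series.
#' @return data.frame with columns cycle_index, phase (frame offset from
#'   cycle start) and alveolar_area_pct.
#' @export
cycleOverlay <- function(series, cycles) {
  fi <- series$frame_index
  out <- lapply(seq_len(nrow(cycles)), function(j) {
    sel <- fi >= cycles$start_frame[j] & fi < cycles$end_frame[j]
    data.frame(cycle_index = cycles$cycle_index[j],
               phase = fi[sel] - cycles$start_frame[j],
               alveolar_area_pct = series$alveolar_area_pct[sel])
  })
  do.call(rbind, out)
}

.SUMMARY_AXES <- c("mean_alveolar_area_pct", "mean_cycle_amplitude",
                   "mean_alveoli_count", "mean_neutrophil_count",
                   "mean_neutrophil_area_pct", "mean_cycle_length")

#' Summarize an experiment for radar-chart comparison
#'
#' The six Kiviat axes: mean alveolar area percentage, mean per-cycle
#' amplitude (max - min), mean alveoli count, mean neutrophil count, mean
#' neutrophil area percentage, and mean cycle length in frames. With no
#' detected cycles the amplitude and cycle-length axes are `NA`.
#'
#' @param series data.frame of per-frame statistics.
#' @param cycles data.frame from [detectCycles()], possibly with zero rows.
#' @return named numeric vector over the six axes.
#' @seealso [normalizeSummaries()]
#' @export
summarizeExperiment <- function(series, cycles) {
  stopifnot(is.data.frame(series), nrow(series) > 0L)
  hasCycles <- !is.null(cycles) && nrow(cycles) > 0L
  c(mean_alveolar_area_pct = mean(series$alveolar_area_pct),
    mean_cycle_amplitude = if (hasCycles)
      mean(cycles$max_alveolar_pct - cycles$min_alveolar_pct) else NA_real_,
    mean_alveoli_count = mean(series$alveoli_count),
    mean_neutrophil_count = mean(series$neutrophil_count),
    mean_neutrophil_area_pct = mean(series$neutrophil_area_pct),
    mean_cycle_length = if (hasCycles)
      mean(cycles$end_frame - cycles$start_frame) else NA_real_)
}

#' Min-max normalize experiment summaries across experiments
#'
#' Rescales each axis to [0, 1] over the loaded experiments so radar-chart
#' shapes are comparable. Axes constant across experiments map to 0.5.
#'
#' @param summaries list of named vectors from [summarizeExperiment()].
#' @return matrix, one row per experiment, one column per axis.
#' @export
normalizeSummaries <- function(summaries) {
  m <- do.call(rbind, lapply(summaries, function(s) s[.SUMMARY_AXES]))
  colnames(m) <- .SUMMARY_AXES
  apply(m, 2L, function(v) {
    r <- range(v, na.rm = TRUE)
    if (!all(is.finite(r)) || r[1L] == r[2L]) rep(0.5, length(v))
    else (v - r[1L]) / (r[2L] - r[1L])
  })
}
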