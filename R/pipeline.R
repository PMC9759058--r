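#' Run the full single-experiment analysis pipeline
#'
#' Per channel: NLM denoising, mask formation, contour extraction, area
#' restriction, then the temporal-consistency filter. Per frame: scalar
#' feature statistics (the interstitial area uses a bright-polarity mask of
#' the denoised interstitial channel with otherwise identical parameters).
#' Finally, respiratory cycles are segmented from the alveolar-area signal
#' and the experiment is summarized.
#'
#' @param interstitial,neutrophil aligned [ChannelSeries-class] inputs.
#' @param paramsInterstitial,paramsNeutrophil [PreprocessParams-class] per
#'   channel.
#' @param restrictionInterstitial,restrictionNeutrophil
#'   [AreaRestriction-class] per channel.
#' @param policyInterstitial,policyNeutrophil [TrackPolicy-class] per
#'   channel.
#' @param track apply the temporal-consistency filter (default TRUE;
#'   requires at least 2 frames).
#' @param smoothingWindow,minCycleLen,prominence cycle-detection settings,
#'   see [detectCycles()].
#' @return list with `stats` (per-frame data.frame), `cycles` (data.frame or
#'   `NULL` if no complete cycle was found, with a warning), `summary`
#'   (named vector), `detections` (post-filter contours per role),
#'   `rejections` (per role) and `masks` (per role).
#' @export
analyzeExperiment <- function(interstitial, neutrophil,
    paramsInterstitial = defaultPreprocessParams("interstitial"),
    paramsNeutrophil = defaultPreprocessParams("neutrophil"),
    restrictionInterstitial = defaultAreaRestriction("interstitial"),
    restrictionNeutrophil = defaultAreaRestriction("neutrophil"),
    policyInterstitial = defaultTrackPolicy("interstitial"),
    policyNeutrophil = defaultTrackPolicy("neutrophil"),
    track = TRUE, smoothingWindow = 3L, minCycleLen = 4L, prominence = 0.5) {
  stopifnot(is(interstitial, "ChannelSeries"), is(neutrophil, "ChannelSeries"))
  if (nFrames(interstitial) != nFrames(neutrophil) ||
      !identical(frameDims(interstitial), frameDims(neutrophil)))
    stop("channel series not aligned")

  segI <- segmentChannel(interstitial, paramsInterstitial,
                         restrictionInterstitial)
  segN <- segmentChannel(neutrophil, paramsNeutrophil, restrictionNeutrophil)

  rejI <- rejN <- NULL
  detI <- segI$detections; detN <- segN$detections
  if (track && nFrames(interstitial) >= 2L) {
    fI <- filterByTemporalConsistency(detI, policyInterstitial)
    fN <- filterByTemporalConsistency(detN, policyNeutrophil)
    detI <- fI$kept; detN <- fN$kept
    rejI <- fI$rejections; rejN <- fN$rejections
  }

  # interstitial (tissue) area: bright-polarity mask, same parameters
  brightParams <- paramsInterstitial
  brightParams@polarity <- "bright_features"
  dims <- frameDims(interstitial)
  stats <- do.call(rbind, lapply(seq_len(nFrames(interstitial)), function(i) {
    computeFrameStats(detI[[i]], detN[[i]],
                      featureMask(segI$denoised[[i]], brightParams),
                      dims, frameIndex = i - 1L)
  }))

  cycles <- tryCatch(
    detectCycles(stats, smoothingWindow, minCycleLen, prominence),
    error = function(e) {
      warning("cycle detection: ", conditionMessage(e),
              " (consider lowering `prominence` or `minCycleLen`)",
              call. = FALSE)
      NULL
    })

  list(stats = stats, cycles = cycles,
       summary = summarizeExperiment(stats, cycles),
       detections = list(interstitial = detI, neutrophil = detN),
       rejections = list(interstitial = rejI, neutrophil = rejN),
       masks = list(interstitial = segI$masks, neutrophil = segN$masks))
}

# nearest-detection distance bookkeeping for recovery scoring
.nearestDetection <- function(contours, x, y) {
  if (length(contours) == 0L) return(list(dist = Inf, area = NA_real_))
  cx <- vapply(contours, function(ct) ct$centroid[[1L]], numeric(1))
  cy <- vapply(contours, function(ct) ct$centroid[[2L]], numeric(1))
  d <- sqrt((cx - x)^2 + (cy - y)^2)
  i <- which.min(d)
  list(dist = d[i], area = contours[[i]]$area)
}

#' Recovery experiment: run the pipeline on a synthetic scene and score it
#'
#' Generates the scene, runs the full analysis, and scores the result
#' against the analytic ground truth: per-frame detected vs true alveoli
#' counts, per-alveolus area errors, the removal rate of injected
#' single-frame transients, the retention rate of persistent neutrophils,
#' and the detected respiratory period vs the configured one.
#'
#' @param config a [SyntheticConfig-class].
#' @param matchRadius maximum centroid distance (px) when pairing a
#'   detection with a ground-truth feature.
#' @param ... passed to [analyzeExperiment()].
#' @return list with elements `analysis` (the [analyzeExperiment()] result),
#'   `alveolusCounts` (per-frame detected counts), `modalAlveolusCount`,
#'   `frameFractionAtTrueCount`, `areaRelErrors` (per matched alveolus per
#'   frame), `meanAreaRelError`, `transientRemovalRate`,
#'   `transientsDetectedPreFilter`, `persistentRetentionRate`,
#'   `cycleLengths`, `meanCycleLength` and `truth`.
#' @export
runRecoveryExperiment <- function(config, matchRadius = 10, ...) {
  scene <- generateScene(config)
  analysis <- analyzeExperiment(scene$interstitial, scene$neutrophil, ...)

  truth <- scene$truth
  n <- nFrames(scene$interstitial)
  detI <- analysis$detections$interstitial
  detN <- analysis$detections$neutrophil

  # alveoli: counts and area errors against analytic truth
  alvCounts <- vapply(detI, length, integer(1))
  tabulateMode <- function(v) as.integer(names(which.max(table(v))))
  alvTruth <- truth[truth$role == "interstitial", , drop = FALSE]
  areaErr <- numeric()
  areaErrId <- character()
  for (t0 in seq_len(n) - 1L) {
    tt <- alvTruth[alvTruth$frame == t0, , drop = FALSE]
    for (j in seq_len(nrow(tt))) {
      nd <- .nearestDetection(detI[[t0 + 1L]], tt$x[j], tt$y[j])
      if (nd$dist <= matchRadius) {
        areaErr <- c(areaErr, abs(nd$area - tt$area[j]) / tt$area[j])
        areaErrId <- c(areaErrId, tt$feature_id[j])
      }
    }
  }

  # persistent neutrophils: retained after the temporal filter?
  neuTruth <- truth[truth$role == "neutrophil" & truth$persistent, , drop = FALSE]
  retained <- 0L
  for (j in seq_len(nrow(neuTruth))) {
    nd <- .nearestDetection(detN[[neuTruth$frame[j] + 1L]],
                            neuTruth$x[j], neuTruth$y[j])
    if (nd$dist <= matchRadius) retained <- retained + 1L
  }
  retentionRate <- if (nrow(neuTruth)) retained / nrow(neuTruth) else NA_real_

  # transients: detectable before the filter, absent after it
  trTruth <- truth[!truth$persistent, , drop = FALSE]
  preSegN <- segmentChannel(scene$neutrophil)$detections
  preDetected <- survived <- 0L
  for (j in seq_len(nrow(trTruth))) {
    fr <- trTruth$frame[j] + 1L
    if (.nearestDetection(preSegN[[fr]], trTruth$x[j], trTruth$y[j])$dist <=
        matchRadius) preDetected <- preDetected + 1L
    if (.nearestDetection(detN[[fr]], trTruth$x[j], trTruth$y[j])$dist <=
        matchRadius) survived <- survived + 1L
  }
  removalRate <- if (nrow(trTruth)) 1 - survived / nrow(trTruth) else NA_real_

  cyc <- analysis$cycles
  cycleLengths <- if (!is.null(cyc)) cyc$end_frame - cyc$start_frame else numeric()

  list(analysis = analysis,
       alveolusCounts = alvCounts,
       modalAlveolusCount = if (length(alvCounts)) tabulateMode(alvCounts) else NA,
       frameFractionAtTrueCount = mean(alvCounts == config@nAlveoli),
       areaRelErrors = areaErr,
       areaRelErrorByAlveolus = if (length(areaErr))
         tapply(areaErr, areaErrId, mean) else numeric(),
       meanAreaRelError = if (length(areaErr)) mean(areaErr) else NA_real_,
       transientRemovalRate = removalRate,
       transientsDetectedPreFilter = preDetected,
       persistentRetentionRate = retentionRate,
       cycleLengths = cycleLengths,
       meanCycleLength = if (length(cycleLengths)) mean(cycleLengths) else NA_real_,
       truth = truth)
}

#' Build and write a provenance manifest
#'
#' `makeManifest()` collects the run parameters, the seed, and MD5 hashes
#' of the input files; identical inputs and parameters give an identical
#' manifest. `writeManifest()` serializes it as JSON; `manifestHash()`
#' returns the MD5 of that canonical serialization.
#'
#' @param parameters named list of run parameters.
#' @param inputPaths character vector of input files to hash.
#' @param seed integer seed recorded in the manifest.
#' @param manifest a manifest list.
#' @param path output JSON path.
#' @return `makeManifest()`: the manifest list; `writeManifest()`:
#'   invisibly `path`; `manifestHash()`: an MD5 string.
#' @export
makeManifest <- function(parameters, inputPaths = character(), seed = NA) {
  hashes <- if (length(inputPaths)) {
    h <- tools::md5sum(inputPaths)
    names(h) <- basename(inputPaths)
    as.list(h[order(names(h))])
  } else list()
  list(parameters = parameters, seed = seed, inputs = hashes)
}

#' @rdname makeManifest
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname makeManifest
#' @export
manifestHash <- function(manifest) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeManifest(manifest, tmp)
  unname(tools::md5sum(tmp))
}

# parameter objects flattened for the manifest
.paramsAsList <- function(obj) {
  sl <- methods::slotNames(class(obj))
  out <- lapply(sl, function(s) methods::slot(obj, s))
  names(out) <- sl
  out
}

#' Paint contour outlines onto a composite RGB frame
#'
#' Draws each contour's boundary pixels in the given color — the overlay
#' rendering of detected features (alveolar contours in white, neutrophils
#' in red by convention).
#'
#' @param composite `h x w x 3` RGB array, 8-bit values.
#' @param contours list of contours, see [extractContours()].
#' @param color length-3 RGB vector, 0--255.
#' @return the painted array.
#' @export
drawContourOverlay <- function(composite, contours,
                               color = c(255, 255, 255)) {
  h <- dim(composite)[1L]; w <- dim(composite)[2L]
  for (ct in contours) {
    xs <- round(ct$polygon[, 1L]); ys <- round(ct$polygon[, 2L])
    ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
    for (k in 1:3)
      composite[cbind(ys[ok] + 1L, xs[ok] + 1L, k)] <- color[k]
  }
  composite
}
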