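#' Accessors for ChannelSeries
#'
#' @param x a [ChannelSeries-class].
#' @param i frame number (1-based).
#' @return `role`: the channel role; `frames`: the list of frame matrices;
#'   `nFrames`: the frame count; `frameDims`: `c(height, width)` in px;
#'   `getFrame`: one frame matrix; `frameRate`: frames/second or `NA`.
#' @name ChannelSeries-accessors
#' @examples
#' cs <- ChannelSeries(matrix(0, 4, 6), "neutrophil")
#' frameDims(cs)  # 4 6
NULL

#' @rdname ChannelSeries-accessors
#' @export
setGeneric("role", function(x) standardGeneric("role"))
#' @rdname ChannelSeries-accessors
#' @export
setMethod("role", "ChannelSeries", function(x) x@role)

#' @rdname ChannelSeries-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname ChannelSeries-accessors
#' @export
setMethod("frames", "ChannelSeries", function(x) x@frames)

#' @rdname ChannelSeries-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname ChannelSeries-accessors
#' @export
setMethod("nFrames", "ChannelSeries", function(x) length(x@frames))

#' @rdname ChannelSeries-accessors
#' @export
setGeneric("frameDims", function(x) standardGeneric("frameDims"))
#' @rdname ChannelSeries-accessors
#' @export
setMethod("frameDims", "ChannelSeries", function(x) dim(x@frames[[1L]]))

#' @rdname ChannelSeries-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname ChannelSeries-accessors
#' @export
setMethod("getFrame", "ChannelSeries", function(x, i) x@frames[[i]])

#' @rdname ChannelSeries-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname ChannelSeries-accessors
#' @export
setMethod("frameRate", "ChannelSeries", function(x) x@frameRate)

setMethod("show", "ChannelSeries", function(object) {
  d <- frameDims(object)
  cat(sprintf("ChannelSeries: %s, %d frame(s) of %d x %d px", object@role,
              nFrames(object), d[1L], d[2L]))
  if (!is.na(object@frameRate))
    cat(sprintf(" @ %.3g fps", object@frameRate))
  cat("\n")
})

setMethod("show", "PreprocessParams", function(object) {
  cat(sprintf(paste0(
    "PreprocessParams (%s)\n",
    "  NLM: h = %g, template = %d, search = %d\n",
    "  mask: blur kernel = %d, threshold = %g, dilate kernel = %d\n"),
    object@polarity, object@nlmStrength, as.integer(object@nlmTemplate),
    as.integer(object@nlmSearch), as.integer(object@blurKernel),
    object@intensityThreshold, as.integer(object@dilateKernel)))
})

setMethod("show", "AreaRestriction", function(object) {
  cat(sprintf("AreaRestriction: [%g, %s] px^2\n", object@minArea,
              if (is.finite(object@maxArea)) sprintf("%g", object@maxArea)
              else "unbounded"))
})

setMethod("show", "TrackPolicy", function(object) {
  cat(sprintf(paste0(
    "TrackPolicy (%s): centroid radius %g px, area tolerance %s\n"),
    object@role, object@centroidRadius,
    if (object@role == "interstitial")
      sprintf("%g (relative)", object@areaToleranceRel)
    else sprintf("%g px^2 (absolute)", object@areaToleranceAbs)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0(
    "SyntheticConfig: %d x %d px, %d frames\n",
    "  breathing: period %g frames, amplitude %g\n",
    "  features: %d alveoli, %d neutrophils (drift %g px/frame), %d transients\n",
    "  noise sigma %g, background %g, seed %d\n"),
    as.integer(object@height), as.integer(object@width),
    as.integer(object@nFrames), object@breathingPeriod,
    object@breathingAmplitude, as.integer(object@nAlveoli),
    as.integer(object@nNeutrophils), object@neutrophilDrift,
    as.integer(object@nTransients), object@noiseSigma,
    object@backgroundInterstitial, as.integer(object@seed)))
})
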