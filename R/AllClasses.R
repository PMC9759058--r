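#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib AlveoTrack, .registration = TRUE
NULL

.CHANNEL_ROLES <- c("interstitial", "neutrophil")
.POLARITIES <- c("dark_features", "bright_features")

#' ChannelSeries: an ordered grayscale frame sequence for one channel
#'
#' Container for one labeled channel of a two-channel intravital recording:
#' either the interstitial channel (dextran-bright tissue, dark alveolar
#' airspaces) or the neutrophil channel (bright labeled cells on a dark
#' background). Frames are numeric matrices holding 8-bit intensities
#' (0--255); all frames share one geometry.
#'
#' @slot role character, `"interstitial"` or `"neutrophil"`.
#' @slot frames list of numeric matrices, one per frame, identical dimensions.
#' @slot frameRate frames per second, `NA_real_` when unknown.
#'
#' @seealso [ChannelSeries()], [loadChannelSeries()], [generateScene()]
#' @export
setClass("ChannelSeries",
  representation(role = "character", frames = "list", frameRate = "numeric"),
  prototype(frameRate = NA_real_))

setValidity("ChannelSeries", function(object) {
  if (length(object@role) != 1L || !object@role %in% .CHANNEL_ROLES)
    return(sprintf("role must be one of: %s", paste(.CHANNEL_ROLES, collapse = ", ")))
  if (length(object@frames) < 1L)
    return("a ChannelSeries needs at least one frame")
  if (!all(vapply(object@frames, is.matrix, logical(1))))
    return("frames must be matrices")
  d <- dim(object@frames[[1L]])
  for (f in object@frames) {
    if (!identical(dim(f), d)) return("inconsistent frame geometry")
    rng <- range(f)
    if (rng[1L] < 0 || rng[2L] > 255) return("intensities must lie in [0, 255]")
  }
  TRUE
})

#' Construct a ChannelSeries
#'
#' @param frames list of numeric matrices (8-bit intensities 0--255), or a
#'   single matrix.
#' @param role `"interstitial"` or `"neutrophil"`.
#' @param frameRate optional frames/second.
#' @return a validated [ChannelSeries-class] object.
#' @examples
#' cs <- ChannelSeries(list(matrix(0, 4, 4), matrix(255, 4, 4)), "interstitial")
#' nFrames(cs)
#' @export
ChannelSeries <- function(frames, role, frameRate = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  new("ChannelSeries", role = role, frames = frames,
      frameRate = as.numeric(frameRate))
}

#' PreprocessParams: per-channel denoising and mask-formation parameters
#'
#' Parameters of the preprocessing chain applied to every frame of one
#' channel: non-local-means denoising (filter strength `h`, odd template and
#' search window sizes), then Gaussian blur, intensity thresholding and
#' morphological dilation to form a binary feature mask. `polarity` selects
#' whether features are darker (`"dark_features"`, alveolar airspaces) or
#' brighter (`"bright_features"`, neutrophils) than the threshold.
#'
#' @slot nlmStrength NLM filter strength h (dimensionless; 0 disables).
#' @slot nlmTemplate odd NLM template (patch) window size, px.
#' @slot nlmSearch odd NLM search window size, px; at least `nlmTemplate`.
#' @slot blurKernel odd Gaussian blur kernel size, px.
#' @slot intensityThreshold 0--255 intensity cutoff.
#' @slot dilateKernel square structuring-element side, px (>= 1).
#' @slot polarity `"dark_features"` or `"bright_features"`.
#'
#' @seealso [defaultPreprocessParams()], [denoiseNLM()], [featureMask()]
#' @export
setClass("PreprocessParams",
  representation(nlmStrength = "numeric", nlmTemplate = "numeric",
                 nlmSearch = "numeric", blurKernel = "numeric",
                 intensityThreshold = "numeric", dilateKernel = "numeric",
                 polarity = "character"))

setValidity("PreprocessParams", function(object) {
  odd <- function(x) x >= 1 && x %% 2 == 1
  if (object@nlmStrength < 0) return("nlmStrength must be >= 0")
  if (!odd(object@nlmTemplate)) return("nlmTemplate must be odd and >= 1")
  if (!odd(object@nlmSearch)) return("nlmSearch must be odd and >= 1")
  if (object@nlmTemplate > object@nlmSearch)
    return("nlmTemplate must not exceed nlmSearch")
  if (!odd(object@blurKernel)) return("blurKernel must be odd and >= 1")
  if (object@intensityThreshold < 0 || object@intensityThreshold > 255)
    return("intensityThreshold must lie in [0, 255]")
  if (object@dilateKernel < 1) return("dilateKernel must be >= 1")
  if (!object@polarity %in% .POLARITIES)
    return(sprintf("polarity must be one of: %s", paste(.POLARITIES, collapse = ", ")))
  TRUE
})

#' AreaRestriction: admissible contour area interval
#'
#' Contours whose pixel area falls outside `[minArea, maxArea]` are treated
#' as false positives and discarded.
#'
#' @slot minArea minimum admissible area, px^2.
#' @slot maxArea maximum admissible area, px^2 (`Inf` for unbounded).
#' @seealso [applyAreaRestriction()], [defaultAreaRestriction()]
#' @export
setClass("AreaRestriction",
  representation(minArea = "numeric", maxArea = "numeric"))

setValidity("AreaRestriction", function(object) {
  if (object@minArea < 0) return("minArea must be >= 0")
  if (object@minArea >= object@maxArea) return("minArea must be < maxArea")
  TRUE
})

#' @param minArea minimum admissible area, px^2.
#' @param maxArea maximum admissible area, px^2; `Inf` for unbounded.
#' @rdname AreaRestriction-class
#' @export
AreaRestriction <- function(minArea = 0, maxArea = Inf) {
  new("AreaRestriction", minArea = as.numeric(minArea),
      maxArea = as.numeric(maxArea))
}

#' TrackPolicy: matching rule of the temporal-consistency filter
#'
#' A detection in frame t is kept only if some detection in frame t-1 or t+1
#' matches it: centroid displacement within `centroidRadius` and area
#' agreement within a relative tolerance (alveoli, whose area swings with
#' breathing) or a fixed absolute tolerance (neutrophils).
#'
#' @slot role channel the policy applies to.
#' @slot areaToleranceRel relative area tolerance in (0, 1], used for the
#'   interstitial (alveolar) role.
#' @slot areaToleranceAbs absolute area tolerance, px^2, used for the
#'   neutrophil role.
#' @slot centroidRadius maximum centroid displacement for a match, px.
#' @seealso [defaultTrackPolicy()], [featuresMatch()],
#'   [filterByTemporalConsistency()]
#' @export
setClass("TrackPolicy",
  representation(role = "character", areaToleranceRel = "numeric",
                 areaToleranceAbs = "numeric", centroidRadius = "numeric"))

setValidity("TrackPolicy", function(object) {
  if (!object@role %in% .CHANNEL_ROLES) return("unknown role")
  if (object@areaToleranceRel <= 0 || object@areaToleranceRel > 1)
    return("areaToleranceRel must lie in (0, 1]")
  if (object@areaToleranceAbs < 0) return("areaToleranceAbs must be >= 0")
  if (object@centroidRadius <= 0) return("centroidRadius must be > 0")
  TRUE
})

#' SyntheticConfig: parametric description of a synthetic two-channel scene
#'
#' Describes a generated intravital video: dark elliptical alveoli on a
#' bright interstitial background whose radii oscillate with a periodic
#' breathing signal s(t) = 1 + A sin(2 pi t / P), bright Gaussian-profile
#' neutrophils drifting across a dark second channel, single-frame transient
#' false blobs, and additive Gaussian sensor noise.
#'
#' @slot height,width frame geometry, px.
#' @slot nFrames number of frames.
#' @slot breathingPeriod breathing period P, frames (>= 4).
#' @slot breathingAmplitude radius modulation amplitude A in [0, 0.9).
#' @slot nAlveoli number of alveoli.
#' @slot alveolusRadiusRange (min, max) baseline semi-axis, px.
#' @slot nNeutrophils number of persistent neutrophils.
#' @slot neutrophilRadiusRange (min, max) blob radius, px.
#' @slot neutrophilDrift drift speed, px/frame.
#' @slot nTransients number of one-frame false blobs.
#' @slot noiseSigma Gaussian noise standard deviation, intensity units.
#' @slot backgroundInterstitial interstitial background intensity, 0--255.
#' @slot seed RNG seed; identical seeds give bit-identical scenes.
#' @seealso [SyntheticConfig()], [generateScene()], [runRecoveryExperiment()]
#' @export
setClass("SyntheticConfig",
  representation(height = "numeric", width = "numeric", nFrames = "numeric",
                 breathingPeriod = "numeric", breathingAmplitude = "numeric",
                 nAlveoli = "numeric", alveolusRadiusRange = "numeric",
                 nNeutrophils = "numeric", neutrophilRadiusRange = "numeric",
                 neutrophilDrift = "numeric", nTransients = "numeric",
                 noiseSigma = "numeric", backgroundInterstitial = "numeric",
                 seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  if (object@height < 16 || object@width < 16)
    return("frames must be at least 16 x 16")
  if (object@nFrames < 1) return("nFrames must be >= 1")
  if (object@breathingPeriod < 4) return("breathingPeriod must be >= 4 frames")
  if (object@breathingAmplitude < 0 || object@breathingAmplitude >= 0.9)
    return("breathingAmplitude must lie in [0, 0.9)")
  if (any(c(object@nAlveoli, object@nNeutrophils, object@nTransients) < 0))
    return("feature counts must be >= 0")
  for (rr in list(object@alveolusRadiusRange, object@neutrophilRadiusRange)) {
    if (length(rr) != 2L || rr[1L] <= 0 || rr[1L] > rr[2L])
      return("radius ranges must be (min, max) with 0 < min <= max")
  }
  if (object@neutrophilDrift < 0) return("neutrophilDrift must be >= 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@backgroundInterstitial < 0 || object@backgroundInterstitial > 255)
    return("backgroundInterstitial must lie in [0, 255]")
  TRUE
})

#' Construct a SyntheticConfig
#'
#' Defaults describe the reference benchmark scene: a 256 x 256, 64-frame
#' video breathing with period 16 frames and radius amplitude 0.2, six
#' well-separated alveoli, five persistent neutrophils drifting at 1
#' px/frame, ten one-frame transient blobs and mild sensor noise.
#'
#' @param height,width frame geometry, px.
#' @param nFrames number of frames.
#' @param breathingPeriod breathing period, frames.
#' @param breathingAmplitude radius modulation amplitude in [0, 0.9).
#' @param nAlveoli number of alveoli.
#' @param alveolusRadiusRange (min, max) baseline semi-axis, px.
#' @param nNeutrophils number of persistent neutrophils.
#' @param neutrophilRadiusRange (min, max) blob radius, px.
#' @param neutrophilDrift drift speed, px/frame.
#' @param nTransients number of one-frame false blobs.
#' @param noiseSigma Gaussian noise sd, intensity units.
#' @param backgroundInterstitial interstitial background intensity.
#' @param seed RNG seed.
#' @return a validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- SyntheticConfig(height = 64, width = 64, nFrames = 8, nAlveoli = 1)
#' @export
SyntheticConfig <- function(height = 256, width = 256, nFrames = 64,
                            breathingPeriod = 16, breathingAmplitude = 0.2,
                            nAlveoli = 6, alveolusRadiusRange = c(18, 28),
                            nNeutrophils = 5, neutrophilRadiusRange = c(4, 7),
                            neutrophilDrift = 1, nTransients = 10,
                            noiseSigma = 5, backgroundInterstitial = 200,
                            seed = 1L) {
  new("SyntheticConfig", height = as.numeric(height), width = as.numeric(width),
      nFrames = as.numeric(nFrames), breathingPeriod = as.numeric(breathingPeriod),
      breathingAmplitude = as.numeric(breathingAmplitude),
      nAlveoli = as.numeric(nAlveoli),
      alveolusRadiusRange = as.numeric(alveolusRadiusRange),
      nNeutrophils = as.numeric(nNeutrophils),
      neutrophilRadiusRange = as.numeric(neutrophilRadiusRange),
      neutrophilDrift = as.numeric(neutrophilDrift),
      nTransients = as.numeric(nTransients), noiseSigma = as.numeric(noiseSigma),
      backgroundInterstitial = as.numeric(backgroundInterstitial),
      seed = as.numeric(seed))
}
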