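#' Default preprocessing parameters per channel role
#'
#' The denoising settings are the reference values of the pipeline: the
#' interstitial/alveolar channel uses NLM filter strength 35 with template
#' window 7 and search window 21; the neutrophil channel uses strength 45
#' with the same windows. Both roles share a Gaussian blur kernel of 11 px
#' and a dilate kernel of 4 px. Alveoli are segmented as dark regions of the
#' interstitial channel (the dextran labels the tissue, airspaces are
#' unlabeled), neutrophils as bright regions of their channel. The intensity
#' cutoff is an exposed hyperparameter: 50 for dark features, 60 for bright
#' features.
#'
#' @param role `"interstitial"` or `"neutrophil"`.
#' @return a [PreprocessParams-class] object.
#' @examples
#' defaultPreprocessParams("interstitial")
#' @export
defaultPreprocessParams <- function(role) {
  if (length(role) != 1L || !role %in% .CHANNEL_ROLES)
    stop("unknown channel role: ", paste(role, collapse = ", "))
  if (role == "interstitial")
    new("PreprocessParams", nlmStrength = 35, nlmTemplate = 7, nlmSearch = 21,
        blurKernel = 11, intensityThreshold = 50, dilateKernel = 4,
        polarity = "dark_features")
  else
    new("PreprocessParams", nlmStrength = 45, nlmTemplate = 7, nlmSearch = 21,
        blurKernel = 11, intensityThreshold = 60, dilateKernel = 4,
        polarity = "bright_features")
}

#' Non-local-means denoising of one frame
#'
#' Averages each pixel with pixels whose surrounding patches look alike,
#' weighting by `exp(-d2 / h^2)` where `d2` is the mean squared difference
#' over the template patch and `h` the filter strength. With `h = 0` the
#' frame is returned unchanged. Deterministic; never changes dimensions;
#' constant frames are preserved exactly.
#'
#' @param frame numeric matrix of 8-bit intensities.
#' @param params a [PreprocessParams-class]; uses `nlmStrength`,
#'   `nlmTemplate`, `nlmSearch`.
#' @return denoised matrix, same dimensions.
#' @export
denoiseNLM <- function(frame, params) {
  stopifnot(is.matrix(frame), is(params, "PreprocessParams"))
  validObject(params)
  if (params@nlmStrength == 0) return(frame)
  nlm_denoise_cpp(frame, params@nlmStrength,
                  as.integer(params@nlmTemplate), as.integer(params@nlmSearch))
}

# sampled, normalized 1-D Gaussian kernel; sigma from the kernel size by the
# conventional sigma = 0.3 ((k - 1)/2 - 1) + 0.8 rule
.gaussianKernel1d <- function(k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  x <- seq(-(k - 1) / 2, (k - 1) / 2)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Form a binary feature mask from a denoised frame
#'
#' The mask pipeline is Gaussian blur (kernel `blurKernel`, replicated
#' edges), then intensity thresholding — pixels strictly below
#' `intensityThreshold` are selected for `dark_features`, strictly above for
#' `bright_features` — then morphological dilation with a square structuring
#' element of side `dilateKernel`.
#'
#' @param frame numeric matrix, typically the output of [denoiseNLM()].
#' @param params a [PreprocessParams-class].
#' @return a 0/1 integer matrix of the same dimensions.
#' @examples
#' p <- defaultPreprocessParams("interstitial")
#' m <- featureMask(matrix(255, 32, 32), p)  # nothing below threshold
#' sum(m)  # 0
#' @export
featureMask <- function(frame, params) {
  stopifnot(is.matrix(frame), is(params, "PreprocessParams"))
  validObject(params)
  k <- as.integer(params@blurKernel)
  g <- .gaussianKernel1d(k)
  blurred <- EBImage::filter2(frame, outer(g, g), boundary = "replicate")
  sel <- if (params@polarity == "dark_features")
    blurred < params@intensityThreshold
  else
    blurred > params@intensityThreshold
  mask <- matrix(0L, nrow(frame), ncol(frame))
  mask[sel] <- 1L
  dk <- as.integer(params@dilateKernel)
  if (dk > 1L && any(mask == 1L))
    mask <- .asBinary(EBImage::dilate(mask, matrix(1, dk, dk)))
  mask
}

.asBinary <- function(m) {
  out <- matrix(0L, nrow(m), ncol(m))
  out[as.matrix(m) > 0] <- 1L
  out
}

#' Preprocess a whole channel: denoise every frame and form its mask
#'
#' @param series a [ChannelSeries-class].
#' @param params a [PreprocessParams-class]; default chosen by the series role.
#' @return list with `denoised` (list of matrices) and `masks` (list of 0/1
#'   matrices), one element per frame.
#' @export
preprocessChannel <- function(series, params = defaultPreprocessParams(role(series))) {
  den <- lapply(frames(series), denoiseNLM, params = params)
  list(denoised = den, masks = lapply(den, featureMask, params = params))
}
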