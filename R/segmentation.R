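#' Extract feature contours from a binary mask
#'
#' Labels the 8-connected foreground components of the mask and returns one
#' contour per component: its external boundary traced clockwise (holes are
#' ignored), its pixel area and its centroid (mean of the component's pixel
#' coordinates). Coordinates are 0-based with x = column, y = row.
#'
#' @param mask 0/1 matrix.
#' @param role `"interstitial"` or `"neutrophil"`, stamped on each contour.
#' @param frameIndex 0-based frame index, stamped on each contour.
#' @return list of contours; each a list with elements `polygon` (n x 2
#'   matrix of x, y vertices), `area` (px^2), `centroid` (x, y), `role`,
#'   `frame_index`. The empty mask yields `list()`.
#' @examples
#' m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
#' ct <- extractContours(m, "interstitial", 0)
#' ct[[1]]$area      # 100
#' ct[[1]]$centroid  # (9.5, 9.5)
#' @export
extractContours <- function(mask, role, frameIndex = 0L) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  if (!role %in% .CHANNEL_ROLES) stop("unknown channel role: ", role)
  lab <- label_components_cpp(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  n <- length(lab$area)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    poly <- lab$polygon[[i]]
    if (nrow(poly) < 3L) { # 1-2 px components: use the pixel-corner square
      x0 <- min(poly[, 1L]) - 0.5; x1 <- max(poly[, 1L]) + 0.5
      y0 <- min(poly[, 2L]) - 0.5; y1 <- max(poly[, 2L]) + 0.5
      poly <- cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
    }
    list(polygon = poly, area = lab$area[i],
         centroid = c(x = lab$cx[i], y = lab$cy[i]),
         role = role, frame_index = as.integer(frameIndex))
  })
}

#' Default area restrictions per channel role
#'
#' Sized to typical feature scales on 8-bit 512 x 512 imagery: alveoli
#' admit 200--26000 px^2, neutrophils 30--800 px^2. Both bounds are exposed
#' hyperparameters.
#'
#' @param role `"interstitial"` or `"neutrophil"`.
#' @return an [AreaRestriction-class].
#' @export
defaultAreaRestriction <- function(role) {
  if (length(role) != 1L || !role %in% .CHANNEL_ROLES)
    stop("unknown channel role: ", paste(role, collapse = ", "))
  if (role == "interstitial") AreaRestriction(200, 26000)
  else AreaRestriction(30, 800)
}

#' Filter contours by admissible area
#'
#' Pure filter: keeps exactly the contours with
#' `minArea <= area <= maxArea`, preserving order and never mutating a
#' contour. Idempotent.
#'
#' @param contours list of contours from [extractContours()].
#' @param restriction an [AreaRestriction-class].
#' @return the admissible sublist.
#' @export
applyAreaRestriction <- function(contours, restriction) {
  stopifnot(is(restriction, "AreaRestriction"))
  validObject(restriction)
  keep <- vapply(contours, function(ct)
    ct$area >= restriction@minArea && ct$area <= restriction@maxArea,
    logical(1))
  contours[keep]
}

#' Segment every frame of a channel
#'
#' Runs denoise -> mask -> contour extraction -> area restriction on each
#' frame of the series.
#'
#' @param series a [ChannelSeries-class].
#' @param params a [PreprocessParams-class].
#' @param restriction an [AreaRestriction-class].
#' @return list with `detections` (per-frame contour lists), `masks` and
#'   `denoised` frames.
#' @export
segmentChannel <- function(series,
                           params = defaultPreprocessParams(role(series)),
                           restriction = defaultAreaRestriction(role(series))) {
  pp <- preprocessChannel(series, params)
  det <- lapply(seq_along(pp$masks), function(i)
    applyAreaRestriction(
      extractContours(pp$masks[[i]], role(series), i - 1L), restriction))
  list(detections = det, masks = pp$masks, denoised = pp$denoised)
}

#' Flatten per-frame contours into a data.frame
#'
#' @param detections per-frame list of contour lists.
#' @return data.frame with columns frame_index, role, area, cx, cy (one row
#'   per contour; zero rows when nothing was detected).
#' @export
contoursToDataFrame <- function(detections) {
  rows <- unlist(detections, recursive = FALSE)
  if (length(rows) == 0L)
    return(data.frame(frame_index = integer(), role = character(),
                      area = numeric(), cx = numeric(), cy = numeric()))
  data.frame(
    frame_index = vapply(rows, `[[`, integer(1), "frame_index"),
    role = vapply(rows, `[[`, character(1), "role"),
    area = vapply(rows, `[[`, numeric(1), "area"),
    cx = vapply(rows, function(ct) ct$centroid[[1L]], numeric(1)),
    cy = vapply(rows, function(ct) ct$centroid[[2L]], numeric(1)))
}
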