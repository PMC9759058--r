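#' Default temporal-consistency policy per channel role
#'
#' Alveoli deform strongly with breathing, so their areas are matched with a
#' relative tolerance (default 0.5) and a centroid radius of 20 px;
#' neutrophils keep a nearly constant footprint, so a fixed absolute
#' tolerance (default 50 px^2) and a centroid radius of 15 px are used.
#'
#' @param role `"interstitial"` or `"neutrophil"`.
#' @return a [TrackPolicy-class].
#' @export
defaultTrackPolicy <- function(role) {
  if (length(role) != 1L || !role %in% .CHANNEL_ROLES)
    stop("unknown channel role: ", paste(role, collapse = ", "))
  if (role == "interstitial")
    new("TrackPolicy", role = role, areaToleranceRel = 0.5,
        areaToleranceAbs = 50, centroidRadius = 20)
  else
    new("TrackPolicy", role = role, areaToleranceRel = 0.5,
        areaToleranceAbs = 50, centroidRadius = 15)
}

#' Do two contours match under a tracking policy?
#'
#' True iff the centroid displacement is within `centroidRadius` and the
#' areas agree: for the interstitial (alveolar) role
#' `|area_a - area_b| <= areaToleranceRel * max(area_a, area_b)` (tolerance
#' for growth/shrinkage across the breath), for neutrophils
#' `|area_a - area_b| <= areaToleranceAbs`.
#'
#' @param a,b contours of the same role, see [extractContours()].
#' @param policy a [TrackPolicy-class].
#' @return logical.
#' @export
featuresMatch <- function(a, b, policy) {
  stopifnot(is(policy, "TrackPolicy"))
  if (!identical(a$role, b$role))
    stop("cannot match contours of different roles")
  d <- sqrt(sum((a$centroid - b$centroid)^2))
  if (d > policy@centroidRadius) return(FALSE)
  if (policy@role == "interstitial")
    abs(a$area - b$area) <= policy@areaToleranceRel * max(a$area, b$area)
  else
    abs(a$area - b$area) <= policy@areaToleranceAbs
}

#' Temporal-consistency filter over per-frame detections
#'
#' A detection at frame t is kept only if it matches (see [featuresMatch()])
#' at least one detection of the *unfiltered* input at frame t-1 or t+1; the
#' first frame checks only its successor and the last only its predecessor.
#' The filter is a single pass — validity is judged against the original
#' neighbors, never against already-filtered lists — which makes it
#' deterministic and order-independent across frames. One-frame false blobs
#' have no matching neighbor and are removed; persistent features whose
#' inter-frame displacement and area change stay within the policy are
#' retained.
#'
#' @param detections per-frame list of contour lists, indexed by consecutive
#'   frames; at least 2 frames.
#' @param policy a [TrackPolicy-class].
#' @return list with `kept` (per-frame sublists of the input, order
#'   preserved) and `rejections` (data.frame: frame_index, cx, cy, area,
#'   reason).
#' @export
filterByTemporalConsistency <- function(detections, policy) {
  stopifnot(is(policy, "TrackPolicy"))
  n <- length(detections)
  if (n < 2L) stop("temporal filter requires >=2 frames")
  anyMatch <- function(ct, neighbors)
    any(vapply(neighbors, featuresMatch, logical(1), a = ct, policy = policy))
  kept <- vector("list", n)
  rej <- list()
  for (t in seq_len(n)) {
    keep <- vapply(detections[[t]], function(ct) {
      (t > 1L && anyMatch(ct, detections[[t - 1L]])) ||
        (t < n && anyMatch(ct, detections[[t + 1L]]))
    }, logical(1))
    kept[[t]] <- detections[[t]][keep]
    for (ct in detections[[t]][!keep])
      rej[[length(rej) + 1L]] <- data.frame(
        frame_index = ct$frame_index, cx = ct$centroid[[1L]],
        cy = ct$centroid[[2L]], area = ct$area,
        reason = "no matching feature in a neighboring frame")
  }
  rejections <- if (length(rej)) do.call(rbind, rej)
  else data.frame(frame_index = integer(), cx = numeric(), cy = numeric(),
                  area = numeric(), reason = character())
  list(kept = kept, rejections = rejections)
}

#' Link detections into persistent track IDs (extension)
#'
#' Greedy nearest-centroid linking across consecutive frames: each contour
#' at frame t is assigned the track of the closest unclaimed contour at
#' frame t-1 that satisfies [featuresMatch()]; unmatched contours open new
#' tracks. This is an optional extension beyond the neighbor-existence
#' filter — the core pipeline does not depend on track identity.
#'
#' @param detections per-frame list of contour lists (ideally the `kept`
#'   output of [filterByTemporalConsistency()]).
#' @param policy a [TrackPolicy-class].
#' @return per-frame list of integer vectors of track IDs, parallel to
#'   `detections`.
#' @export
linkTracks <- function(detections, policy) {
  stopifnot(is(policy, "TrackPolicy"))
  nextId <- 1L
  ids <- vector("list", length(detections))
  for (t in seq_along(detections)) {
    cur <- detections[[t]]
    ids[[t]] <- integer(length(cur))
    prev <- if (t > 1L) detections[[t - 1L]] else list()
    claimed <- logical(length(prev))
    # process current contours by their best match distance (greedy)
    if (length(cur) && length(prev)) {
      dmat <- vapply(prev, function(q) vapply(cur, function(p)
        sqrt(sum((p$centroid - q$centroid)^2)), numeric(1)),
        numeric(length(cur)))
      dmat <- matrix(dmat, nrow = length(cur))
      ord <- order(apply(dmat, 1L, min))
      for (i in ord) {
        cand <- order(dmat[i, ])
        for (j in cand) {
          if (!claimed[j] &&
              featuresMatch(cur[[i]], prev[[j]], policy)) {
            ids[[t]][i] <- ids[[t - 1L]][j]
            claimed[j] <- TRUE
            break
          }
        }
      }
    }
    for (i in seq_along(cur)) {
      if (ids[[t]][i] == 0L) {
        ids[[t]][i] <- nextId
        nextId <- nextId + 1L
      }
    }
  }
  ids
}
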