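# evaluate expr with a locally seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(as.integer(seed))
  expr
}

# fold a coordinate path into [lo, hi] by reflection (triangle wave)
.reflectPath <- function(p, lo, hi) {
  L <- hi - lo
  if (L <= 0) return(rep(lo, length(p)))
  q <- (p - lo) %% (2 * L)
  lo + ifelse(q <= L, q, 2 * L - q)
}

# paint a filled ellipse (value) into frame; cx, cy, rx, ry in 0-based px
.paintEllipse <- function(frame, cx, cy, rx, ry, value) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- max(0L, floor(cx - rx)); x1 <- min(w - 1L, ceiling(cx + rx))
  y0 <- max(0L, floor(cy - ry)); y1 <- min(h - 1L, ceiling(cy + ry))
  if (x1 < x0 || y1 < y0) return(frame)
  xs <- x0:x1; ys <- y0:y1
  m <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
  sub <- frame[ys + 1L, xs + 1L, drop = FALSE]
  sub[m] <- value
  frame[ys + 1L, xs + 1L] <- sub
  frame
}

# add a Gaussian-profile blob (max-composited) into frame
.paintBlob <- function(frame, cx, cy, sigma, peak) {
  h <- nrow(frame); w <- ncol(frame)
  ext <- ceiling(3.5 * sigma)
  x0 <- max(0L, floor(cx - ext)); x1 <- min(w - 1L, ceiling(cx + ext))
  y0 <- max(0L, floor(cy - ext)); y1 <- min(h - 1L, ceiling(cy + ext))
  if (x1 < x0 || y1 < y0) return(frame)
  xs <- x0:x1; ys <- y0:y1
  prof <- peak * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma^2))
  frame[ys + 1L, xs + 1L] <- pmax(frame[ys + 1L, xs + 1L, drop = FALSE], prof)
  frame
}

.ALVEOLUS_INTENSITY <- 10   # dark airspace on the bright interstitium
.NEUTROPHIL_BACKGROUND <- 10
.NEUTROPHIL_PEAK <- 230
# bright-mask threshold (60) crossed at radius r: sigma = r / sqrt(2 ln(peak/60))
.NEUTROPHIL_SIGMA_FACTOR <- 1 / sqrt(2 * log(.NEUTROPHIL_PEAK / 60))

#' Generate a synthetic two-channel intravital scene with ground truth
#'
#' The interstitial channel is a uniform bright background carrying dark
#' filled ellipses (alveolar airspaces) whose semi-axes scale with the
#' breathing signal `s(t) = 1 + A sin(2 pi t / P)`; the neutrophil channel
#' is dark with bright Gaussian-profile blobs drifting at a constant speed
#' (reflecting off the frame margins), plus single-frame transient blobs at
#' seeded random frames and positions. Transients are placed at least 30 px
#' from every persistent neutrophil path so their later removal by the
#' temporal filter is unambiguous. Additive Gaussian noise is clipped to
#' [0, 255]. Identical seeds give bit-identical scenes; the global RNG
#' state is left untouched.
#'
#' Ground truth records, per frame and feature, the analytic centroid and
#' area: `pi a b s(t)^2` for an alveolus with baseline semi-axes (a, b),
#' and `pi r^2` for a neutrophil of radius r (the disk above the bright
#' mask threshold in the clean rendering).
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `interstitial` and `neutrophil`
#'   ([ChannelSeries-class]), `truth` (data.frame: frame, feature_id, role,
#'   x, y, area, persistent) and `config`.
#' @examples
#' sc <- generateScene(SyntheticConfig(height = 64, width = 64, nFrames = 6,
#'                                     nAlveoli = 1, nNeutrophils = 1,
#'                                     nTransients = 0, noiseSigma = 0))
#' nFrames(sc$interstitial)
#' @export
generateScene <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  .withSeed(config@seed, .generateSceneImpl(config))
}

.generateSceneImpl <- function(config) {
  h <- as.integer(config@height); w <- as.integer(config@width)
  n <- as.integer(config@nFrames)
  A <- config@breathingAmplitude; P <- config@breathingPeriod

  # --- place alveoli (no overlap at peak inflation) ---
  na <- as.integer(config@nAlveoli)
  rr <- config@alveolusRadiusRange
  aAx <- stats::runif(na, rr[1L], rr[2L])
  bAx <- stats::runif(na, rr[1L], rr[2L])
  acx <- numeric(na); acy <- numeric(na)
  if (na > 0L) {
    placed <- FALSE
    for (restart in seq_len(60L)) { # restart greedy placement on dead ends
      acx[] <- acy[] <- 0
      done <- 0L
      for (i in seq_len(na)) {
        m <- max(aAx[i], bAx[i]) * (1 + A) + 2
        if (w - 1 - m <= m || h - 1 - m <= m) stop("cannot place features")
        ok <- FALSE
        for (try in seq_len(200L)) {
          cx <- stats::runif(1, m, w - 1 - m)
          cy <- stats::runif(1, m, h - 1 - m)
          if (i == 1L || all(sqrt((cx - acx[seq_len(i - 1L)])^2 +
                                  (cy - acy[seq_len(i - 1L)])^2) >
                             (max(aAx[i], bAx[i]) +
                              pmax(aAx[seq_len(i - 1L)], bAx[seq_len(i - 1L)])) *
                             (1 + A) + 4)) {
            acx[i] <- cx; acy[i] <- cy; ok <- TRUE; break
          }
        }
        if (!ok) break
        done <- i
      }
      if (done == na) { placed <- TRUE; break }
    }
    if (!placed) stop("cannot place features")
  }

  # --- persistent neutrophils: radius, reflected linear drift ---
  nn <- as.integer(config@nNeutrophils)
  nr <- config@neutrophilRadiusRange
  nrad <- stats::runif(nn, nr[1L], nr[2L])
  nx <- vector("list", nn); ny <- vector("list", nn)
  ts <- seq_len(n) - 1
  for (i in seq_len(nn)) {
    m <- nrad[i] + 3
    x0 <- stats::runif(1, m, w - 1 - m)
    y0 <- stats::runif(1, m, h - 1 - m)
    th <- stats::runif(1, 0, 2 * pi)
    nx[[i]] <- .reflectPath(x0 + ts * config@neutrophilDrift * cos(th), m, w - 1 - m)
    ny[[i]] <- .reflectPath(y0 + ts * config@neutrophilDrift * sin(th), m, h - 1 - m)
  }

  # --- transients: one-frame blobs far from every persistent path ---
  nt <- as.integer(config@nTransients)
  trad <- stats::runif(nt, nr[1L], nr[2L])
  tframe <- if (nt > 0L) sample.int(n, nt, replace = TRUE) - 1L else integer()
  tx <- numeric(nt); ty <- numeric(nt)
  clearance <- 30 # 2 x default neutrophil centroid radius
  for (i in seq_len(nt)) {
    m <- trad[i] + 3
    ok <- FALSE
    for (try in seq_len(5000L)) {
      cx <- stats::runif(1, m, w - 1 - m)
      cy <- stats::runif(1, m, h - 1 - m)
      farFromPersistent <- all(vapply(seq_len(nn), function(j)
        min(sqrt((cx - nx[[j]])^2 + (cy - ny[[j]])^2)) > clearance,
        logical(1)))
      # only transients in the same or adjacent frames can interact
      near <- seq_len(i - 1L)
      near <- near[abs(tframe[near] - tframe[i]) <= 1L]
      farFromTransients <- length(near) == 0L ||
        all(sqrt((cx - tx[near])^2 + (cy - ty[near])^2) > clearance)
      if (farFromPersistent && farFromTransients) {
        tx[i] <- cx; ty[i] <- cy; ok <- TRUE; break
      }
    }
    if (!ok) stop("cannot place features")
  }

  # --- render frames and assemble ground truth ---
  interFrames <- vector("list", n)
  neutFrames <- vector("list", n)
  truth <- vector("list", n)
  for (t0 in ts) {
    s <- 1 + A * sin(2 * pi * t0 / P)
    fi <- matrix(config@backgroundInterstitial, h, w)
    for (i in seq_len(na))
      fi <- .paintEllipse(fi, acx[i], acy[i], aAx[i] * s, bAx[i] * s,
                          .ALVEOLUS_INTENSITY)
    fn <- matrix(.NEUTROPHIL_BACKGROUND, h, w)
    for (i in seq_len(nn))
      fn <- .paintBlob(fn, nx[[i]][t0 + 1L], ny[[i]][t0 + 1L],
                       nrad[i] * .NEUTROPHIL_SIGMA_FACTOR, .NEUTROPHIL_PEAK)
    for (i in which(tframe == t0))
      fn <- .paintBlob(fn, tx[i], ty[i], trad[i] * .NEUTROPHIL_SIGMA_FACTOR,
                       .NEUTROPHIL_PEAK)
    if (config@noiseSigma > 0) {
      fi <- fi + matrix(stats::rnorm(h * w, 0, config@noiseSigma), h, w)
      fn <- fn + matrix(stats::rnorm(h * w, 0, config@noiseSigma), h, w)
    }
    interFrames[[t0 + 1L]] <- round(pmin(pmax(fi, 0), 255))
    neutFrames[[t0 + 1L]] <- round(pmin(pmax(fn, 0), 255))

    gt <- list()
    if (na > 0L)
      gt[[length(gt) + 1L]] <- data.frame(
        frame = t0, feature_id = sprintf("alv%d", seq_len(na)),
        role = "interstitial", x = acx[seq_len(na)], y = acy[seq_len(na)],
        area = pi * aAx * bAx * s^2, persistent = TRUE)
    if (nn > 0L)
      gt[[length(gt) + 1L]] <- data.frame(
        frame = t0, feature_id = sprintf("neu%d", seq_len(nn)),
        role = "neutrophil",
        x = vapply(nx, `[[`, numeric(1), t0 + 1L),
        y = vapply(ny, `[[`, numeric(1), t0 + 1L),
        area = pi * nrad^2, persistent = TRUE)
    sel <- which(tframe == t0)
    if (length(sel))
      gt[[length(gt) + 1L]] <- data.frame(
        frame = t0, feature_id = sprintf("tr%d", sel), role = "neutrophil",
        x = tx[sel], y = ty[sel], area = pi * trad[sel]^2, persistent = FALSE)
    truth[[t0 + 1L]] <- if (length(gt)) do.call(rbind, gt) else NULL
  }

  truthDf <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truthDf))
    truthDf <- data.frame(frame = integer(), feature_id = character(),
                          role = character(), x = numeric(), y = numeric(),
                          area = numeric(), persistent = logical())
  rownames(truthDf) <- NULL
  list(interstitial = ChannelSeries(interFrames, "interstitial"),
       neutrophil = ChannelSeries(neutFrames, "neutrophil"),
       truth = truthDf, config = config)
}

#' Write a synthetic scene through the standard I/O path
#'
#' Saves the two channels as numbered PNG (or TIFF) frame directories —
#' exactly what [loadChannelSeries()] consumes — plus the ground truth as
#' CSV.
#'
#' @param scene list from [generateScene()].
#' @param directory output root; channels go to `interstitial/` and
#'   `neutrophil/` subdirectories.
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, `directory`.
#' @export
writeScene <- function(scene, directory, format = c("png", "tiff")) {
  format <- match.arg(format)
  writeChannelSeries(scene$interstitial, file.path(directory, "interstitial"),
                     format = format)
  writeChannelSeries(scene$neutrophil, file.path(directory, "neutrophil"),
                     format = format)
  utils::write.csv(scene$truth, file.path(directory, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(directory)
}
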