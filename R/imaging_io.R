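#' Load an image sequence directory as a ChannelSeries
#'
#' Reads all grayscale TIFF/PNG frames in `directory` whose names match
#' `pattern`. Frame order is determined by the first integer run in each
#' filename (numeric, not lexicographic), so unpadded counters such as
#' `f_2.tif`, `f_10.tif` sort correctly. Images deeper than 8 bits are
#' linearly rescaled to 8-bit over the full range of their bit depth.
#'
#' @param directory path holding the frame files.
#' @param role `"interstitial"` or `"neutrophil"`.
#' @param pattern filename glob, default all TIFF/PNG files.
#' @param collapse how to treat multi-channel source images: `FALSE`
#'   (default) rejects them; `TRUE` collapses to grayscale by averaging the
#'   color channels.
#' @param frameRate optional frames/second metadata.
#' @return a [ChannelSeries-class] with frames ordered by ascending index.
#' @seealso [writeChannelSeries()], [combineChannels()]
#' @export
loadChannelSeries <- function(directory, role, pattern = "*",
                              collapse = FALSE, frameRate = NA_real_) {
  files <- list.files(directory, pattern = utils::glob2rx(pattern))
  files <- files[grepl("\\.(tif|tiff|png)$", files, ignore.case = TRUE)]
  if (length(files) == 0L)
    stop("no frames found in '", directory, "'")
  idx <- regmatches(files, regexpr("[0-9]+", files))
  if (length(idx) != length(files))
    stop("ambiguous frame order: filename without a numeric index")
  idx <- as.numeric(idx)
  if (anyDuplicated(idx))
    stop("ambiguous frame order: duplicate frame index")
  files <- files[order(idx)]
  fr <- lapply(file.path(directory, files), .readGrayFrame, collapse = collapse)
  d <- dim(fr[[1L]])
  if (!all(vapply(fr, function(f) identical(dim(f), d), logical(1))))
    stop("inconsistent frame geometry")
  ChannelSeries(fr, role = role, frameRate = frameRate)
}

# read one TIFF/PNG file as an 8-bit grayscale matrix
.readGrayFrame <- function(path, collapse = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      if (!collapse)
        stop("multi-channel image '", basename(path),
             "'; pass collapse = TRUE to average channels")
      img <- apply(img, c(1L, 2L), mean)
    }
    if (max(img) > 255) # deeper than 8 bits: full-scale 16-bit mapping
      img <- img * (255 / 65535)
    round(img)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE] # drop alpha
      if (dim(img)[3L] > 1L && !collapse)
        stop("multi-channel image '", basename(path),
             "'; pass collapse = TRUE to average channels")
      img <- apply(img, c(1L, 2L), mean)
    }
    round(img * 255)
  } else {
    stop("unsupported image format: ", ext)
  }
}

#' Write a ChannelSeries as numbered image files
#'
#' Writes one grayscale 8-bit file per frame, named
#' `<prefix>_<zero-padded index>.<format>`, so the directory round-trips
#' through [loadChannelSeries()] bit-exactly.
#'
#' @param series a [ChannelSeries-class].
#' @param directory output directory (created if absent).
#' @param prefix filename prefix.
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, the written file paths.
#' @export
writeChannelSeries <- function(series, directory, prefix = "frame",
                               format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  n <- nFrames(series)
  width <- max(3L, nchar(as.character(n - 1L)))
  paths <- character(n)
  for (i in seq_len(n)) {
    p <- file.path(directory, sprintf("%s_%0*d.%s", prefix, width, i - 1L,
                                      if (format == "tiff") "tif" else "png"))
    img <- getFrame(series, i) / 255
    if (format == "png") png::writePNG(img, p)
    else tiff::writeTIFF(img, p, bits.per.sample = 8L)
    paths[i] <- p
  }
  invisible(paths)
}

#' Composite the two channels into RGB frames
#'
#' Stacks the channels into color frames with the conventional assignment:
#' the interstitial channel fills the blue plane, the neutrophil channel the
#' red plane, and the green plane is all zeros. The mapping is lossless:
#' extracting the blue and red planes reconstructs both inputs exactly.
#'
#' @param interstitial,neutrophil aligned [ChannelSeries-class] objects with
#'   equal frame counts and geometry.
#' @return list of `height x width x 3` arrays with 8-bit values in the
#'   order red, green, blue.
#' @examples
#' i <- ChannelSeries(matrix(200, 2, 2), "interstitial")
#' n <- ChannelSeries(matrix(0, 2, 2), "neutrophil")
#' combineChannels(i, n)[[1]][1, 1, ]  # (0, 0, 200)
#' @export
combineChannels <- function(interstitial, neutrophil) {
  stopifnot(is(interstitial, "ChannelSeries"), is(neutrophil, "ChannelSeries"))
  if (nFrames(interstitial) != nFrames(neutrophil) ||
      !identical(frameDims(interstitial), frameDims(neutrophil)))
    stop("channel series not aligned")
  d <- frameDims(interstitial)
  lapply(seq_len(nFrames(interstitial)), function(i) {
    rgb <- array(0, dim = c(d[1L], d[2L], 3L))
    rgb[, , 1L] <- getFrame(neutrophil, i)
    rgb[, , 3L] <- getFrame(interstitial, i)
    rgb
  })
}

#' Write composite RGB frames as PNG files
#'
#' @param composites list of RGB arrays from [combineChannels()].
#' @param directory output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
writeCompositeFrames <- function(composites, directory, prefix = "composite") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  width <- max(3L, nchar(as.character(length(composites) - 1L)))
  paths <- vapply(seq_along(composites), function(i) {
    p <- file.path(directory, sprintf("%s_%0*d.png", prefix, width, i - 1L))
    png::writePNG(composites[[i]] / 255, p)
    p
  }, character(1))
  invisible(paths)
}

.FRAME_STATS_COLS <- c("frame_index", "alveolar_area_pct", "alveoli_count",
                       "airspace_per_alveolus_pct", "neutrophil_count",
                       "neutrophil_area_pct", "interstitial_area_pct")

#' Write and read per-frame feature tables
#'
#' `writeFeatureTable()` serializes a frame-statistics table (one row per
#' frame, fixed column order: frame_index, alveolar_area_pct, alveoli_count,
#' airspace_per_alveolus_pct, neutrophil_count, neutrophil_area_pct,
#' interstitial_area_pct) as CSV, plus a parallel JSON file (same fields,
#' one object per frame) next to it for front-end consumption.
#' `readFeatureTable()` reads the CSV back; round-trips agree to at least
#' six decimal places.
#'
#' @param stats data.frame of per-frame statistics, see [computeFrameStats()].
#' @param path output CSV path; the JSON sibling replaces the extension.
#' @return `writeFeatureTable()`: invisibly, the CSV path;
#'   `readFeatureTable()`: the data.frame.
#' @export
writeFeatureTable <- function(stats, path) {
  if (is.null(stats) || nrow(stats) == 0L)
    stop("cannot write an empty feature table")
  stopifnot(all(.FRAME_STATS_COLS %in% names(stats)))
  stats <- stats[, .FRAME_STATS_COLS]
  utils::write.csv(format(stats, digits = 15L, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(stats, sub("\\.[^.]*$", ".json", path),
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Export per-frame contours as JSON
#'
#' One array element per frame; each holds the frame's contours with fields
#' `polygon` (list of `[x, y]` vertices, 0-based), `area`, `centroid` and
#' `role` — the overlay-rendering schema.
#'
#' @param detections per-frame list of contour lists, see [extractContours()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeContoursJSON <- function(detections, path) {
  out <- lapply(seq_along(detections), function(i) {
    list(frame_index = i - 1L,
         contours = lapply(detections[[i]], function(ct) {
           list(polygon = unname(apply(ct$polygon, 1L, function(v) c(v[1L], v[2L]),
                                       simplify = FALSE)),
                area = ct$area, centroid = ct$centroid, role = ct$role)
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a respiratory-cycle table as CSV
#'
#' Columns: cycle_index, start_frame, end_frame, min_alveolar_pct,
#' max_alveolar_pct.
#'
#' @param cycles data.frame from [detectCycles()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeCycleTable <- function(cycles, path) {
  utils::write.csv(cycles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
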