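# File formats: 16-bit grayscale TIFF (single or multi-page) with a JSON
# sidecar carrying physical pixel size, and CSV tables for point patterns,
# tracks and dwells. All tabular writers have documented headers and
# round-trip exactly at double precision via the JSON sidecars.

TIFF_SCALE <- 65535

#' Write an image (or stack) as 16-bit grayscale TIFF
#'
#' Counts are stored as `counts / scale` in the unit-interval convention of
#' the TIFF writer; the scale and pixel size are recorded both in the TIFF
#' description tag and in a JSON sidecar (`<path>.json`).
#'
#' @param image A `netarch_image`, numeric matrix, or list of them (written
#'   as a multi-page TIFF).
#' @param path Output path (.tif).
#' @param pixel_size Pixel size (um); defaults to the image attribute.
#' @param scale Counts mapped to the 16-bit full scale.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, pixel_size = NULL, scale = TIFF_SCALE) {
  frames <- if (is.list(image)) image else list(image)
  pixel_size <- pixel_size %||% attr(frames[[1]], "pixel_size")
  if (is.null(pixel_size)) stop_param("`pixel_size` is required")
  norm <- lapply(frames, function(f) {
    m <- pmin(pmax(unclass(f) / scale, 0), 1)
    attributes(m) <- list(dim = dim(m))
    m
  })
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = pixel_size, scale = scale,
                            n_frames = length(frames)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image (or stack) written by [write_image()]
#'
#' @param path Path to the TIFF.
#' @return A `netarch_image` (or list of them for a multi-page file), in
#'   counts, with `pixel_size` attribute.
#' @export
read_image <- function(path) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  ps <- meta$pixel_size_um
  scale <- meta$scale %||% TIFF_SCALE
  if (is.null(ps)) stop_param("no pixel-size sidecar (%s) for %s", meta_path, path)
  out <- lapply(frames, function(f) {
    m <- f * scale
    structure(round(m), pixel_size = ps,
              class = c("netarch_image", "matrix", "array"))
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a point pattern as CSV (+ ground-truth JSON sidecar)
#'
#' Columns: `x_um`, `y_um`. Field geometry and any generator ground truth
#' go to `<path>.json`.
#' @param pattern A [point_pattern()].
#' @param path Output path (.csv).
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.csv(data.frame(x_um = pattern$points[, 1],
                              y_um = pattern$points[, 2]),
                   path, row.names = FALSE)
  jsonlite::write_json(list(field = pattern$field[c("width", "height", "pixel_size")],
                            ground_truth = pattern$ground_truth),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point pattern written by [write_pattern_csv()]
#' @param path Path to the CSV.
#' @param field Optional [field_spec()] overriding the sidecar.
#' @export
read_pattern_csv <- function(path, field = NULL) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  gt <- NULL
  if (is.null(field)) {
    if (!file.exists(meta_path)) stop_param("no field sidecar for %s; supply `field`", path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    field <- field_spec(meta$field$width, meta$field$height, meta$field$pixel_size)
    gt <- meta$ground_truth
  }
  point_pattern(cbind(d$x_um, d$y_um), field, ground_truth = gt)
}

#' Write tracks as CSV
#'
#' Columns: `track_id`, `frame`, `x_um`, `y_um`, `intensity`; the frame
#' interval and ground truth go to `<path>.json`.
#' @param tracks A [track_set()].
#' @param path Output path (.csv).
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(data.frame(track_id = tracks$track_id, frame = tracks$frame,
                              x_um = tracks$x, y_um = tracks$y,
                              intensity = tracks$intensity),
                   path, row.names = FALSE)
  jsonlite::write_json(list(frame_interval_s = attr(tracks, "frame_interval"),
                            ground_truth = attr(tracks, "ground_truth")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tracks written by [write_tracks_csv()] (or any conforming CSV)
#' @param path Path to the CSV.
#' @param frame_interval Frame interval (s); defaults to the sidecar value.
#' @export
read_tracks_csv <- function(path, frame_interval = NULL) {
  d <- utils::read.csv(path)
  names(d) <- sub("^x_um$", "x", sub("^y_um$", "y", names(d)))
  meta_path <- paste0(path, ".json")
  gt <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    frame_interval <- frame_interval %||% meta$frame_interval_s
    gt <- meta$ground_truth
  }
  if (is.null(frame_interval)) stop_param("`frame_interval` is required (no sidecar)")
  track_set(d, frame_interval, ground_truth = gt)
}

#' Write dwell times as CSV
#'
#' Columns: `frames`, `duration_s`, `censored`, `location`; frame interval,
#' threshold and ground truth in `<path>.json`.
#' @param dwells A [dwell_set()].
#' @param path Output path (.csv).
#' @export
write_dwells_csv <- function(dwells, path) {
  utils::write.csv(data.frame(frames = dwells$frames,
                              duration_s = dwells$duration,
                              censored = dwells$censored,
                              location = dwells$location),
                   path, row.names = FALSE)
  jsonlite::write_json(list(frame_interval_s = attr(dwells, "frame_interval"),
                            threshold_frames = attr(dwells, "threshold_frames"),
                            ground_truth = attr(dwells, "ground_truth")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read dwell times written by [write_dwells_csv()]
#' @param path Path to the CSV.
#' @export
read_dwells_csv <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop_param("no sidecar for %s", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dwell_set(d$frames, meta$frame_interval_s, censored = d$censored,
            location = d$location,
            threshold_frames = meta$threshold_frames %||% 6L,
            ground_truth = meta$ground_truth)
}
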