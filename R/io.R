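# Frame ingestion and CSV interchange. Frames are 8-bit grayscale matrices
# (0-255); RGB input is converted by luminance. CSV is the single
# interchange format: headers mandatory, angles in degrees, 0-based pixel
# coordinates.

#' Read a frame sequence
#'
#' Reads every PNG/TIFF image in a directory, sorted lexicographically, or
#' a single image file. Color images are converted to grayscale by
#' luminance (0.2126 R + 0.7152 G + 0.0722 B); intensities are returned on
#' the 0-255 scale.
#'
#' @param path directory of images, or one image file.
#' @return list of numeric matrices (rows = y, columns = x).
#' @export
readFrames <- function(path) {
  files <- if (dir.exists(path)) {
    f <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE))
    if (!length(f)) stop("no PNG/TIFF frames found in ", path)
    f
  } else if (file.exists(path)) path
  else stop("no such file or directory: ", path)
  lapply(files, function(fn) {
    img <- EBImage::readImage(fn)
    d <- EBImage::imageData(img)
    if (length(dim(d)) == 3) {
      d <- 0.2126 * d[, , 1] + 0.7152 * d[, , 2] + 0.0722 * d[, , 3]
    }
    # EBImage stores x in dim 1: transpose to rows = y
    t(d) * 255
  })
}

#' Write a frame sequence as zero-padded PNGs
#'
#' @param frames list of matrices (0-255 gray levels).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written file names.
#' @export
writeFrames <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, sprintf("%s_%05d.png", prefix,
                                  seq_along(frames) - 1L))
  for (k in seq_along(frames))
    EBImage::writeImage(EBImage::Image(t(frames[[k]] / 255)), files[k])
  invisible(files)
}

#' Write a binary mask as a 0/255 PNG (debug aid)
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @export
writeMask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Detection and trajectory CSV interchange
#'
#' \code{writeDetections}/\code{readDetections} handle the per-frame head
#' detection table; \code{writeTracks}/\code{readTracks} the trajectory
#' table (one row per track per frame). Reading back a written
#' \code{\link{TrackSet-class}} reproduces it exactly.
#'
#' @param detections detection data.frame.
#' @param tracks a \code{\link{TrackSet-class}}.
#' @param path CSV path.
#' @param nTracks,startFrame used by \code{readTracks} to rebuild the
#'   object (inferred from the table when NULL).
#' @name csv-io
NULL

#' @rdname csv-io
#' @export
writeDetections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readDetections <- function(path) {
  utils::read.csv(path)
}

#' @rdname csv-io
#' @export
writeTracks <- function(tracks, path) {
  st <- if (is(tracks, "TrackSet")) tracks@states else tracks
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readTracks <- function(path, nTracks = NULL, startFrame = NULL) {
  st <- utils::read.csv(path, colClasses = c(status = "character"))
  st$frame <- as.integer(st$frame)
  st$track_id <- as.integer(st$track_id)
  if (is.null(nTracks)) nTracks <- length(unique(st$track_id))
  if (is.null(startFrame)) startFrame <- min(st$frame)
  new("TrackSet", states = st, nTracks = as.integer(nTracks),
      startFrame = as.integer(startFrame))
}

#' Write ground truth to CSV
#'
#' @param gt ground-truth data.frame.
#' @param path CSV path.
#' @export
writeGroundTruth <- function(gt, path) {
  utils::write.csv(gt, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  gt <- utils::read.csv(path)
  gt$occluded <- as.logical(gt$occluded)
  gt
}
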