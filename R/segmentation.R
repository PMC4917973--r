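# Moving-region segmentation: median background model, intensity
# differencing, and mask cleaning (fill holes -> drop small blobs ->
# binary median smoothing).

#' Median background model
#'
#' Builds a static background image as the per-pixel median of the first
#' \code{n} frames. Moving fish occupy any one pixel for only a short time,
#' so the temporal median recovers the empty tank. For even \code{n} the
#' lower of the two middle order statistics is used, which keeps every
#' background pixel an attainable gray level.
#'
#' @param frames list of 2-D numeric matrices, all the same shape.
#' @param n number of leading frames to use (default: all).
#' @return numeric matrix of the background, same shape as the frames.
#' @export
computeBackground <- function(frames, n = length(frames)) {
  if (!is.list(frames) || length(frames) == 0)
    stop("'frames' must be a non-empty list of matrices")
  if (n < 1 || n > length(frames))
    stop("'n' must be between 1 and the number of frames")
  d <- dim(frames[[1]])
  for (f in frames[seq_len(n)])
    if (!identical(dim(f), d)) stop("all frames must share the same shape")
  stack <- matrix(vapply(frames[seq_len(n)], as.numeric, numeric(prod(d))),
                  nrow = prod(d), ncol = n)
  k <- (n + 1L) %/% 2L  # lower median for even n
  bg <- .rowKthSmallest(stack, as.integer(k))
  matrix(bg, nrow = d[1], ncol = d[2])
}

#' Segment the moving regions of one frame
#'
#' A pixel is foreground exactly when the absolute difference between the
#' background model and the frame exceeds \code{tG} (strict inequality).
#'
#' @param frame 2-D numeric matrix (gray levels).
#' @param bg background matrix from \code{\link{computeBackground}}.
#' @param tG intensity threshold in gray levels.
#' @return logical matrix: the raw moving-region mask.
#' @export
segmentFrame <- function(frame, bg, tG) {
  if (!identical(dim(frame), dim(bg)))
    stop("frame and background shapes differ")
  abs(bg - frame) > tG
}

#' Clean a raw moving-region mask
#'
#' Applies, in order: hole filling (flood fill of background regions not
#' reachable from the image border), removal of connected components
#' smaller than \code{minBlobArea}, and a binary median smoothing with an
#' odd \code{medianKernel} x \code{medianKernel} window.
#'
#' @param mask logical matrix.
#' @param minBlobArea smallest component area kept, in pixels.
#' @param medianKernel odd window side for the median smoothing; 1 disables.
#' @return logical matrix: the cleaned mask.
#' @export
cleanMask <- function(mask, minBlobArea = 30, medianKernel = 3) {
  stopifnot(is.logical(mask), medianKernel >= 1, medianKernel %% 2 == 1)
  m <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (minBlobArea > 0 && any(m > 0)) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < minBlobArea)
    if (length(drop)) m[lab %in% drop] <- 0L
  }
  if (medianKernel > 1 && any(m > 0))
    m <- .binaryMedian(m, medianKernel)
  m > 0
}

# binary median filter: majority vote over a k x k window (k odd), pixels
# outside the image counting as background
.binaryMedian <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  r <- (k - 1L) %/% 2L
  acc <- matrix(0L, nr, nc)
  for (dr in -r:r) for (dc in -r:r) {
    rs <- (1L + max(0L, dr)):(nr + min(0L, dr))
    cs <- (1L + max(0L, dc)):(nc + min(0L, dc))
    acc[rs - dr, cs - dc] <- acc[rs - dr, cs - dc] + m[rs, cs]
  }
  matrix(as.integer(acc > (k * k) %/% 2L), nr, nc)
}
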