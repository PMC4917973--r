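# Overlay rendering: a direction triangle and a position dot per track,
# colored by track id, drawn into an RGB copy of the frame.

#' Render a tracking overlay for one frame
#'
#' Draws, for every track state, a filled triangle whose apex points along
#' the estimated head direction and a small white dot at the detected
#' position, colored per track id.
#'
#' @param frame numeric matrix (gray 0-255).
#' @param statesAtFrame data.frame of track states for this frame
#'   (\code{track_id}, \code{x}, \code{y}, \code{theta_deg}).
#' @param nTracks total number of tracks (for a stable color map).
#' @param size triangle size in pixels.
#' @return an \code{EBImage::Image} in color mode, x-major as usual for
#'   EBImage.
#' @export
renderOverlay <- function(frame, statesAtFrame, nTracks = NULL, size = 12) {
  h <- nrow(frame); w <- ncol(frame)
  g <- frame / 255
  rgb <- array(rep(g, 3), dim = c(h, w, 3))
  if (nrow(statesAtFrame) > 0) {
    if (is.null(nTracks)) nTracks <- max(statesAtFrame$track_id)
    cols <- grDevices::col2rgb(grDevices::rainbow(nTracks)) / 255
    for (t in seq_len(nrow(statesAtFrame))) {
      x <- statesAtFrame$x[t]; y <- statesAtFrame$y[t]
      th <- statesAtFrame$theta_deg[t]
      if (is.na(th)) th <- 0
      a <- th * pi / 180
      apex <- c(x + size * cos(a), y + size * sin(a))
      base1 <- c(x + 0.5 * size * cos(a + 2.5), y + 0.5 * size * sin(a + 2.5))
      base2 <- c(x + 0.5 * size * cos(a - 2.5), y + 0.5 * size * sin(a - 2.5))
      px <- .fillTriangle(apex, base1, base2, w, h)
      if (nrow(px)) {
        cc <- cols[, statesAtFrame$track_id[t]]
        for (ch in 1:3)
          rgb[cbind(px[, 2] + 1L, px[, 1] + 1L, ch)] <- cc[ch]
      }
      # white position dot
      for (dx in -1:1) for (dy in -1:1) {
        xx <- round(x) + dx; yy <- round(y) + dy
        if (xx >= 0 && xx < w && yy >= 0 && yy < h)
          rgb[yy + 1L, xx + 1L, ] <- 1
      }
    }
  }
  EBImage::rgbImage(EBImage::Image(t(rgb[, , 1])),
                    EBImage::Image(t(rgb[, , 2])),
                    EBImage::Image(t(rgb[, , 3])))
}

# integer pixels inside a triangle (0-based), clipped to the image
.fillTriangle <- function(p1, p2, p3, w, h) {
  xs <- max(0, floor(min(p1[1], p2[1], p3[1]))):min(w - 1, ceiling(max(p1[1], p2[1], p3[1])))
  ys <- max(0, floor(min(p1[2], p2[2], p3[2]))):min(h - 1, ceiling(max(p1[2], p2[2], p3[2])))
  if (!length(xs) || !length(ys)) return(matrix(integer(0), 0, 2))
  pg <- expand.grid(x = xs, y = ys)
  sgn <- function(a, b, p)
    (p$x - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p$y - b[2])
  d1 <- sgn(p1, p2, pg); d2 <- sgn(p2, p3, pg); d3 <- sgn(p3, p1, pg)
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  inside <- !(neg & pos)
  cbind(pg$x[inside], pg$y[inside])
}
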