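# Head direction estimation: second-order Gaussian-derivative (Hessian)
# responses at the head endpoint over several scales; the scale maximizing
# the scale-normalized determinant of the Hessian is kept, and the head
# direction is the eigenvector of the smaller-magnitude eigenvalue, its
# 180-degree ambiguity resolved with a local skeleton tangent. All angles
# use image coordinates: x right (columns), y down (rows), degrees in
# [0, 360).

.gauss1d <- function(u, s) exp(-u^2 / (2 * s^2)) / (sqrt(2 * pi) * s)

# image patch centered at 0-based (x, y) with replicate padding
.patchAt <- function(img, x, y, rad) {
  nr <- nrow(img); nc <- ncol(img)
  rs <- pmin(pmax((y - rad):(y + rad) + 1L, 1L), nr)
  cs <- pmin(pmax((x - rad):(x + rad) + 1L, 1L), nc)
  padded <- (y - rad < 0) || (y + rad > nr - 1L) ||
    (x - rad < 0) || (x + rad > nc - 1L)
  list(patch = img[rs, cs, drop = FALSE], padded = padded)
}

#' Hessian of the image at a point and scale
#'
#' Computes the three second-order Gaussian-derivative responses L_xx,
#' L_xy, L_yy at pixel (x, y) with derivative-kernel standard deviation
#' \code{s} (kernels truncated at 4s, border handled by replication and
#' flagged), the scale-normalized determinant
#' doh = (L_xx L_yy - L_xy^2) s^4, and the eigen-decomposition ordered by
#' eigenvalue magnitude.
#'
#' @param image 2-D numeric matrix.
#' @param x,y 0-based pixel coordinates.
#' @param s scale in pixels.
#' @return a \code{hessianResult} list: \code{lxx}, \code{lxy}, \code{lyy},
#'   \code{scale}, \code{doh}, \code{lambda1}, \code{lambda2}
#'   (|lambda1| >= |lambda2|), \code{alpha1}, \code{alpha2} (unit
#'   eigenvectors, alpha1 for lambda1), \code{borderPadded}.
#' @export
hessianAt <- function(image, x, y, s) {
  stopifnot(s > 0)
  rad <- as.integer(ceiling(4 * s))
  u <- (-rad):rad
  g <- .gauss1d(u, s)
  g1 <- (-u / s^2) * g
  g2 <- ((u^2 - s^2) / s^4) * g
  # truncation leaves small moment errors; enforce the discrete moment
  # conditions exactly (unit mass; unit first moment; zero mass and
  # second moment 2 for the second derivative) so flat and polynomial
  # patches give exact responses
  g <- g / sum(g)
  g1 <- g1 / abs(sum(g1 * u))
  g2 <- g2 - mean(g2)
  g2 <- 2 * g2 / sum(g2 * u^2)
  pp <- .patchAt(image, as.integer(round(x)), as.integer(round(y)), rad)
  P <- pp$patch
  # rows of P vary in y, columns in x: K[y, x] = ky(y) kx(x)
  lxx <- sum(P * (g %o% g2))
  lxy <- sum(P * (g1 %o% g1))
  lyy <- sum(P * (g2 %o% g))
  doh <- (lxx * lyy - lxy^2) * s^4

  tr <- lxx + lyy
  disc <- sqrt(max(0, (lxx - lyy)^2 + 4 * lxy^2))
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  if (abs(e2) > abs(e1)) { tmp <- e1; e1 <- e2; e2 <- tmp }
  evec <- function(lam) {
    # (H - lam I) v = 0 for symmetric 2x2
    v1 <- c(lxy, lam - lxx)
    v2 <- c(lam - lyy, lxy)
    v <- if (sum(v1^2) >= sum(v2^2)) v1 else v2
    n <- sqrt(sum(v^2))
    if (n == 0) c(1, 0) else v / n
  }
  a1 <- evec(e1)
  a2 <- c(-a1[2], a1[1])  # orthogonal complement, exactly unit
  structure(list(lxx = lxx, lxy = lxy, lyy = lyy, scale = s, doh = doh,
                 lambda1 = e1, lambda2 = e2, alpha1 = a1, alpha2 = a2,
                 borderPadded = pp$padded),
            class = "hessianResult")
}

#' Select the Hessian scale maximizing |DoH|
#'
#' Evaluates \code{\link{hessianAt}} at every scale and returns the one
#' with the largest absolute scale-normalized determinant; ties go to the
#' smaller scale. When every |DoH| is zero (flat patch) the result is
#' flagged degenerate.
#'
#' @inheritParams hessianAt
#' @param scales strictly increasing positive scales.
#' @return list with \code{sHat}, \code{result} (the winning
#'   \code{hessianResult}) and \code{degenerate}.
#' @export
selectScale <- function(image, x, y, scales) {
  stopifnot(length(scales) >= 1, all(scales > 0),
            !is.unsorted(scales, strictly = TRUE))
  best <- NULL; bestAbs <- -1
  for (s in scales) {
    h <- hessianAt(image, x, y, s)
    if (abs(h$doh) > bestAbs) { bestAbs <- abs(h$doh); best <- h }
  }
  list(sHat = best$scale, result = best,
       degenerate = bestAbs <= sqrt(.Machine$double.eps))
}

#' Head direction from a Hessian result
#'
#' The direction is the angle of alpha2, the eigenvector of the
#' smaller-magnitude eigenvalue (the axis of least curvature, i.e. along
#' the head). Its 180-degree sign ambiguity is resolved by requiring a
#' positive dot product with \code{hint}, a unit vector pointing from the
#' body interior outward through the endpoint (see
#' \code{\link{skeletonHint}}). Patches whose eigenvalue magnitude ratio
#' |lambda1|/|lambda2| falls below \code{anisotropyMin} are treated as
#' isotropic and return NA (direction unavailable) rather than a noise
#' angle.
#'
#' @param result a \code{hessianResult}.
#' @param hint numeric length-2 unit vector (x, y).
#' @param anisotropyMin minimum eigenvalue magnitude ratio.
#' @return angle in degrees in [0, 360), or NA when degenerate.
#' @export
estimateTheta <- function(result, hint, anisotropyMin = 1.2) {
  stopifnot(inherits(result, "hessianResult"), length(hint) == 2)
  l1 <- result$lambda1; l2 <- result$lambda2
  if (l1 == 0 && l2 == 0) return(NA_real_)
  if (l2 != 0 && abs(l1) / abs(l2) < anisotropyMin) return(NA_real_)
  v <- result$alpha2
  if (sum(v * hint) < 0) v <- -v
  (atan2(v[2], v[1]) * 180 / pi) %% 360
}

#' Outward skeleton tangent at an endpoint
#'
#' Walks \code{k} pixels inward from the endpoint along its skeleton branch
#' and returns the unit vector from that pixel toward the endpoint, i.e.
#' pointing out of the body through the head tip. Falls back to the
#' farthest reachable pixel on branches shorter than \code{k}.
#'
#' @param graph a \code{\link{SkeletonGraph-class}}.
#' @param x,y 0-based endpoint coordinates.
#' @param k how many pixels inward to anchor the tangent (default 5).
#' @return unit numeric vector (x, y), or NULL when the endpoint is not on
#'   a branch (isolated pixel).
#' @export
skeletonHint <- function(graph, x, y, k = 5L) {
  for (br in graph@branches) {
    p <- br$path
    n <- nrow(p)
    if (n < 2) next
    if (p[1, "x"] == x && p[1, "y"] == y) {
      a <- p[min(k + 1L, n), ]
    } else if (p[n, "x"] == x && p[n, "y"] == y) {
      a <- p[max(1L, n - k), ]
    } else next
    v <- c(x - a[["x"]], y - a[["y"]])
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    return(v / nv)
  }
  NULL
}

#' Estimate directions for a table of head detections
#'
#' Runs scale selection and orientation estimation at each detection.
#' Estimation operates on the foreground-bright version of the image (the
#' image is inverted when \code{darkFish}), so eigenvalue signs are
#' consistent across polarities. Detections with isotropic or flat patches
#' keep \code{theta_deg = NA}; the tracker treats them with an
#' uninformative direction term rather than dropping them.
#'
#' @param detections data.frame from \code{\link{classifyHeads}}.
#' @param image the frame matrix (gray levels 0-255).
#' @param graph the frame's \code{\link{SkeletonGraph-class}} (for hints).
#' @param scales Hessian scales.
#' @param anisotropyMin see \code{\link{estimateTheta}}.
#' @param darkFish TRUE when fish are darker than the background.
#' @return the detections with \code{theta_deg} filled (NA when degenerate).
#' @export
estimateHeadDirections <- function(detections, image, graph,
                                   scales = c(2, 3, 4, 6, 8),
                                   anisotropyMin = 1.2, darkFish = TRUE) {
  if (nrow(detections) == 0) return(detections)
  img <- if (darkFish) 255 - image else image
  for (t in seq_len(nrow(detections))) {
    sel <- selectScale(img, detections$x[t], detections$y[t], scales)
    if (sel$degenerate) next
    hint <- skeletonHint(graph, detections$x[t], detections$y[t])
    if (is.null(hint)) next
    detections$theta_deg[t] <- estimateTheta(sel$result, hint, anisotropyMin)
  }
  detections
}
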