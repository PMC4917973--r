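# Ground-truthed synthetic swimming-fish sequences. Fish are tapered
# capsules (head cap wider than tail cap) moving with a bounded-turn-rate
# random heading walk inside a reflecting arena; ground truth records the
# head-cap center, heading and an occlusion flag (body envelopes of two
# fish overlapping). All randomness derives from one integer seed, split
# by fish id so adding a fish never perturbs the others' paths.

.defaultFish <- function() {
  list(length = 60, headHalfWidth = 8, tailHalfWidth = 2,
       bodyGray = 60, backgroundGray = 200)
}

.defaultMotion <- function() {
  list(speed = 6, jitter = 2, maxTurn = 15)
}

.fishSeed <- function(seed, fishId) {
  as.integer((as.double(seed) * 7919 + fishId * 104729) %% 2147483647)
}

.frameSeed <- function(seed, frame) {
  as.integer((as.double(seed) * 31337 + frame * 65537 + 11) %% 2147483647)
}

# body segment of one fish: head-cap center A and tail-cap center B
.bodySegment <- function(x, y, thetaDeg, fish) {
  th <- thetaDeg * pi / 180
  u <- c(cos(th), sin(th))
  core <- fish$length - fish$headHalfWidth - fish$tailHalfWidth
  list(A = c(x, y), B = c(x, y) - core * u)
}

# minimum distance between two segments (a1-a2, b1-b2)
.segSegDist <- function(a1, a2, b1, b2) {
  clamp <- function(v) pmin(pmax(v, 0), 1)
  d1 <- a2 - a1; d2 <- b2 - b1; r <- a1 - b1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a == 0 && e == 0) return(sqrt(sum(r * r)))
  if (a == 0) { s <- 0; t <- clamp(f / e) }
  else {
    c0 <- sum(d1 * r)
    if (e == 0) { t <- 0; s <- clamp(-c0 / a) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den != 0) clamp((b * f - c0 * e) / den) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- clamp(-c0 / a) }
      else if (t > 1) { t <- 1; s <- clamp((b - c0) / a) }
    }
  }
  p1 <- a1 + s * d1; p2 <- b1 + t * d2
  sqrt(sum((p1 - p2)^2))
}

# occlusion flags for one frame of positions/headings
.occlusionFlags <- function(xs, ys, ths, fish) {
  n <- length(xs)
  occ <- rep(FALSE, n)
  if (n < 2) return(occ)
  segs <- lapply(seq_len(n), function(i) .bodySegment(xs[i], ys[i], ths[i], fish))
  thr <- 2 * fish$headHalfWidth
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- .segSegDist(segs[[i]]$A, segs[[i]]$B, segs[[j]]$A, segs[[j]]$B)
    if (d < thr) { occ[i] <- TRUE; occ[j] <- TRUE }
  }
  occ
}

#' Simulate ground-truth fish trajectories
#'
#' Headings follow a bounded random walk (per-frame turn uniform in
#' [-maxTurn, maxTurn]), speeds are mean +/- uniform jitter, and positions
#' integrate heading x speed with reflection at the walls. Each fish draws
#' from its own seed-derived random stream, so adding a fish never perturbs
#' the others' paths.
#'
#' With \code{avoid = TRUE} the arena is tiled into one reflecting
#' territory per fish; bodies then stay strictly farther apart than the
#' occlusion threshold, so the truth is occlusion-free by construction
#' (the regime of a sparse, non-interacting group). Engineered crossings
#' override this for designated pairs in adjacent territories: both are
#' steered toward the midpoint of their shared edge on a schedule, pass
#' through each other, and are steered home -- producing deterministic,
#' temporally localized occlusions. With \code{avoid = FALSE} all fish
#' share the arena and interact freely.
#'
#' The occluded flag marks frames where two body envelopes come closer
#' than twice the head half-width.
#'
#' @param nFish,nFrames population and sequence length.
#' @param arena c(width, height) in pixels.
#' @param fish fish geometry list (see package defaults: length 60 px,
#'   head half-width 8, tail half-width 2).
#' @param motion list with \code{speed}, \code{jitter}, \code{maxTurn}.
#' @param seed integer seed.
#' @param avoid logical; confine each fish to its own territory so that no
#'   occlusion can occur outside engineered crossings.
#' @param crossings number of engineered pairwise crossings (0 disables).
#' @return ground-truth data.frame: \code{frame}, \code{fish_id}, \code{x},
#'   \code{y}, \code{theta_deg}, \code{occluded}.
#' @export
simulateTrajectories <- function(nFish, nFrames, arena = c(600, 600),
                                 fish = .defaultFish(),
                                 motion = .defaultMotion(),
                                 seed = 1L, avoid = FALSE, crossings = 0L) {
  stopifnot(nFish >= 1, nFrames >= 1)
  margin <- fish$length + 5
  if (arena[1] - 2 * margin < 10 || arena[2] - 2 * margin < 10)
    stop("arena too small for the fish geometry")
  ncol0 <- ceiling(sqrt(nFish))
  nrow0 <- ceiling(nFish / ncol0)

  # one reflecting box per fish: its territory when avoid = TRUE,
  # the whole arena otherwise
  boxW <- arena[1] / ncol0
  boxH <- arena[2] / nrow0
  if (avoid && nFish > 1 && (boxW < 2 * margin + 20 || boxH < 2 * margin + 20))
    stop("arena too small to give every fish a territory")
  boxes <- lapply(seq_len(nFish) - 1L, function(k) {
    if (!avoid || nFish == 1) return(c(0, arena[1], 0, arena[2]))
    r <- k %/% ncol0; c0 <- k %% ncol0
    c(c0 * boxW, (c0 + 1) * boxW, r * boxH, (r + 1) * boxH)
  })
  ctr <- t(vapply(boxes, function(b)
    c((b[1] + b[2]) / 2, (b[3] + b[4]) / 2), numeric(2)))

  x <- ctr[, 1]; y <- ctr[, 2]
  th <- numeric(nFish)
  turns <- matrix(0, nFrames, nFish)
  speeds <- matrix(0, nFrames, nFish)
  for (i in seq_len(nFish)) {
    set.seed(.fishSeed(seed, i))
    th[i] <- stats::runif(1, 0, 360)
    turns[, i] <- stats::runif(nFrames, -motion$maxTurn, motion$maxTurn)
    speeds[, i] <- pmax(0.5, motion$speed +
                          stats::runif(nFrames, -motion$jitter, motion$jitter))
  }

  # engineered crossings: pairs in horizontally adjacent territories meet
  # at the midpoint of their shared edge
  crossPlan <- NULL
  if (crossings > 0 && nFish > 1) {
    cand <- list()
    for (r in seq_len(nrow0) - 1L) {
      cc <- 0L
      while (cc + 1L < ncol0) {
        a <- r * ncol0 + cc + 1L
        b <- a + 1L
        if (b <= nFish) cand[[length(cand) + 1L]] <- c(a, b)
        cc <- cc + 2L
      }
    }
    nPairs <- min(crossings, length(cand))
    if (nPairs > 0) {
      lo <- min(60, max(10, nFrames %/% 3))
      hi <- max(lo, nFrames - 45)
      when <- round(seq(lo, hi, length.out = nPairs))
      crossPlan <- lapply(seq_len(nPairs), function(k) {
        a <- cand[[k]][1]; b <- cand[[k]][2]
        list(a = a, b = b, frame = when[k],
             wx = (ctr[a, 1] + ctr[b, 1]) / 2,
             wy = (ctr[a, 2] + ctr[b, 2]) / 2)
      })
    }
  }

  steerTo <- function(i, tx, ty, rate) {
    want <- atan2(ty - y[i], tx - x[i]) * 180 / pi
    d <- ((want - th[i] + 180) %% 360) - 180
    (th[i] + sign(d) * min(abs(d), rate)) %% 360
  }

  gt <- vector("list", nFrames)
  for (f in seq_len(nFrames) - 1L) {
    if (f > 0) {
      for (i in seq_len(nFish)) {
        th[i] <- (th[i] + turns[f, i]) %% 360
        sp <- speeds[f, i]

        approaching <- FALSE
        if (!is.null(crossPlan)) {
          for (cp in crossPlan) {
            if ((i == cp$a || i == cp$b) &&
                f >= cp$frame - 40 && f <= cp$frame) {
              th[i] <- steerTo(i, cp$wx, cp$wy, 3 * motion$maxTurn)
              approaching <- TRUE
            }
          }
        }

        b <- boxes[[i]]
        insideBox <- x[i] >= b[1] + margin && x[i] <= b[2] - margin &&
          y[i] >= b[3] + margin && y[i] <= b[4] - margin
        if (approaching || (avoid && !insideBox)) {
          # free flight across the arena (crossing, or homing after one)
          if (!approaching && avoid && !insideBox)
            th[i] <- steerTo(i, ctr[i, 1], ctr[i, 2], 3 * motion$maxTurn)
          b <- c(0, arena[1], 0, arena[2])
        }

        lox <- b[1] + margin; hix <- b[2] - margin
        loy <- b[3] + margin; hiy <- b[4] - margin
        theta <- th[i]
        nx <- x[i] + sp * cos(theta * pi / 180)
        ny <- y[i] + sp * sin(theta * pi / 180)
        if (nx < lox || nx > hix) {
          theta <- (180 - theta) %% 360
          nx <- x[i] + sp * cos(theta * pi / 180)
        }
        if (ny < loy || ny > hiy) {
          theta <- (-theta) %% 360
          ny <- y[i] + sp * sin(theta * pi / 180)
        }
        x[i] <- min(max(nx, lox), hix)
        y[i] <- min(max(ny, loy), hiy)
        th[i] <- theta
      }
    }
    occ <- .occlusionFlags(x, y, th, fish)
    gt[[f + 1L]] <- data.frame(frame = f, fish_id = seq_len(nFish),
                               x = x, y = y, theta_deg = th, occluded = occ)
  }
  out <- do.call(rbind, gt)
  rownames(out) <- NULL
  out
}

# signed distance to an uneven capsule (convex hull of two circles):
# head-cap center A radius r1, tail-cap center B radius r2 <= r1.
# px, py vectorized.
.unevenCapsuleSd <- function(px, py, A, B, r1, r2) {
  bx <- B[1] - A[1]; by <- B[2] - A[2]
  h <- sqrt(bx^2 + by^2)
  if (h == 0) return(sqrt((px - A[1])^2 + (py - A[2])^2) - r1)
  # rotate into frame with B - A along +y
  ux <- bx / h; uy <- by / h
  qx <- (px - A[1]) * uy - (py - A[2]) * ux
  qy <- (px - A[1]) * ux + (py - A[2]) * uy
  qx <- abs(qx)
  b <- (r1 - r2) / h
  a <- sqrt(pmax(0, 1 - b^2))
  k <- qx * (-b) + qy * a
  sd <- qx * a + qy * b - r1          # lateral hull face
  lo <- k < 0
  hi <- k > a * h
  sd[lo] <- sqrt(qx[lo]^2 + qy[lo]^2) - r1
  sd[hi] <- sqrt(qx[hi]^2 + (qy[hi] - h)^2) - r2
  sd
}

#' Render one frame of fish
#'
#' Each fish is drawn as a tapered capsule (an uneven capsule: head cap of
#' radius headHalfWidth at the ground-truth position, tail cap of radius
#' tailHalfWidth, width tapering linearly between them) at constant body
#' gray on a constant background, then Gaussian pixel noise is added and
#' the result clipped to [0, 255]. A pixel belongs to a fish body when its
#' center lies inside the capsule (signed distance <= 0).
#'
#' @param gtFrame one frame of ground truth (rows of the table from
#'   \code{\link{simulateTrajectories}}).
#' @param arena c(width, height) pixels.
#' @param fish fish geometry list.
#' @param noiseSigma Gaussian noise standard deviation (gray levels).
#' @param seed integer seed for the noise.
#' @return numeric matrix (nrow = height, ncol = width), gray levels 0-255.
#' @export
renderFrame <- function(gtFrame, arena = c(600, 600), fish = .defaultFish(),
                        noiseSigma = 2, seed = 1L) {
  w <- arena[1]; h <- arena[2]
  img <- matrix(fish$backgroundGray, h, w)
  core <- fish$length - fish$headHalfWidth - fish$tailHalfWidth
  for (t in seq_len(nrow(gtFrame))) {
    seg <- .bodySegment(gtFrame$x[t], gtFrame$y[t], gtFrame$theta_deg[t], fish)
    r1 <- fish$headHalfWidth; r2 <- fish$tailHalfWidth
    x0 <- max(0, floor(min(seg$A[1], seg$B[1]) - r1 - 1))
    x1 <- min(w - 1, ceiling(max(seg$A[1], seg$B[1]) + r1 + 1))
    y0 <- max(0, floor(min(seg$A[2], seg$B[2]) - r1 - 1))
    y1 <- min(h - 1, ceiling(max(seg$A[2], seg$B[2]) + r1 + 1))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    pg <- expand.grid(yy = ys, xx = xs)
    sd <- .unevenCapsuleSd(pg$xx, pg$yy, seg$A, seg$B, r1, r2)
    inside <- sd <= 0
    if (any(inside))
      img[cbind(pg$yy[inside] + 1L, pg$xx[inside] + 1L)] <- fish$bodyGray
  }
  if (noiseSigma > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(w * h, 0, noiseSigma), h, w)
    img[img < 0] <- 0; img[img > 255] <- 255
  }
  img
}

#' Build a named synthetic benchmark
#'
#' Profiles: \code{easy} (10 fish, collision avoidance, occlusion-free
#' truth), \code{occluding} (20 fish with engineered pairwise crossings),
#' \code{dense} (40 fish, free interaction). Regenerating with the same
#' seed reproduces frames and ground truth bit-exactly.
#'
#' @param profile one of \code{"easy"}, \code{"occluding"}, \code{"dense"}.
#' @param seed integer seed.
#' @param nFrames sequence length (profile default when NULL).
#' @param noiseSigma Gaussian pixel noise sd (gray levels).
#' @return a \code{\link{FishBenchmark-class}}.
#' @export
makeBenchmark <- function(profile = c("easy", "occluding", "dense"),
                          seed = 1L, nFrames = NULL, noiseSigma = 2) {
  profile <- match.arg(profile)
  fish <- .defaultFish()
  motion <- .defaultMotion()
  cfg <- switch(profile,
    easy = list(nFish = 10L, nFrames = 200L, arena = c(840, 630),
                avoid = TRUE, crossings = 0L),
    occluding = list(nFish = 20L, nFrames = 200L, arena = c(1000, 800),
                     avoid = TRUE, crossings = 5L),
    dense = list(nFish = 40L, nFrames = 100L, arena = c(900, 900),
                 avoid = FALSE, crossings = 5L))
  if (!is.null(nFrames)) cfg$nFrames <- as.integer(nFrames)
  gt <- simulateTrajectories(cfg$nFish, cfg$nFrames, cfg$arena, fish, motion,
                             seed = seed, avoid = cfg$avoid,
                             crossings = cfg$crossings)
  frames <- lapply(seq_len(cfg$nFrames) - 1L, function(f)
    renderFrame(gt[gt$frame == f, , drop = FALSE], cfg$arena, fish,
                noiseSigma, seed = .frameSeed(seed, f)))
  new("FishBenchmark", frames = frames, groundTruth = gt,
      seed = as.integer(seed),
      params = c(cfg, list(fish = fish, motion = motion,
                           noiseSigma = noiseSigma, profile = profile)))
}
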