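# Fixture builders and independent oracles shared across tests. All masks
# are logical matrices [row = y + 1, col = x + 1], 0-based coordinates.

rectMask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

diskMask <- function(n = 61, cx = 30, cy = 30, r = 20) {
  g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  matrix((g$r - cy)^2 + (g$c - cx)^2 <= r^2, n, n)
}

# default fish geometry used by the renderer
fishGeom <- function() fishHeadTracker:::.defaultFish()

# render a single fish and return image + analytic quantities
oneFish <- function(x = 100, y = 80, theta = 30, noise = 0, seed = 1,
                    arena = c(200, 160)) {
  gt1 <- data.frame(frame = 0L, fish_id = 1L, x = x, y = y,
                    theta_deg = theta, occluded = FALSE)
  img <- renderFrame(gt1, arena = arena, fish = fishGeom(),
                     noiseSigma = noise, seed = seed)
  bg <- matrix(fishGeom()$backgroundGray, arena[2], arena[1])
  list(img = img, bg = bg, gt = gt1)
}

# independent capsule footprint: a pixel is inside when its distance to
# some point of the tapered body (radius interpolated along the axis) is
# within that radius; dense parameter sampling
capsuleFootprintOracle <- function(gt1, arena, fish, nt = 2000) {
  th <- gt1$theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  core <- fish$length - fish$headHalfWidth - fish$tailHalfWidth
  A <- c(gt1$x, gt1$y)
  B <- A - core * u
  tfrac <- seq(0, 1, length.out = nt)
  cx <- A[1] + (B[1] - A[1]) * tfrac
  cy <- A[2] + (B[2] - A[2]) * tfrac
  # hull of circles: radius varies so the tangent line shifts; sampling
  # circles densely approximates the hull footprint
  rr <- fish$headHalfWidth + (fish$tailHalfWidth - fish$headHalfWidth) * tfrac
  m <- matrix(FALSE, arena[2], arena[1])
  xs <- 0:(arena[1] - 1); ys <- 0:(arena[2] - 1)
  for (k in seq_len(nt)) {
    d2 <- outer((ys - cy[k])^2, (xs - cx[k])^2, "+")
    m <- m | (d2 <= rr[k]^2)
  }
  m
}

# brute-force exact Euclidean distance to the nearest background pixel
bruteEdt <- function(mask, x, y) {
  bg <- which(!mask, arr.ind = TRUE)
  min(sqrt((bg[, 1] - (y + 1))^2 + (bg[, 2] - (x + 1))^2))
}

# exhaustive assignment oracle: maximum number of finite pairs, then
# minimum total cost
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms(v[-i]), function(p) c(v[i], p))))
}

bruteAssignment <- function(A) {
  flip <- nrow(A) > ncol(A)
  if (flip) A <- t(A)
  n <- nrow(A); m <- ncol(A)
  best <- Inf; bestk <- -1
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    costs <- A[cbind(seq_len(n), sel)]
    ok <- is.finite(costs)
    tot <- sum(costs[ok]); k <- sum(ok)
    if (k > bestk || (k == bestk && tot < best)) { best <- tot; bestk <- k }
  }
  list(nPairs = bestk, cost = if (bestk > 0) best else 0)
}
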