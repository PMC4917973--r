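test_that("boundary parameterization assigns U = 1..L once per boundary pixel", {
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  f <- parameterizeBoundary(m)
  expect_equal(f$U[2, 2], 1)
  expect_equal(unname(f$boundaryLength), 1)

  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  f <- parameterizeBoundary(m)
  expect_equal(unname(f$boundaryLength), 8)
  expect_setequal(f$U[!is.na(f$U)], 1:8)
  expect_true(is.na(f$U[3, 3]))  # center is interior

  # 40 x 10 rectangle: 96 boundary pixels
  m <- rectMask(20, 50, 6, 15, 6, 45)
  f <- parameterizeBoundary(m)
  expect_equal(unname(f$boundaryLength), 2 * 40 + 2 * 10 - 4)
  expect_setequal(f$U[f$boundary], seq_len(96))
})

test_that("empty masks yield empty fields and graphs", {
  m <- matrix(FALSE, 5, 5)
  f <- propagateArrivalTimes(parameterizeBoundary(m))
  expect_true(all(is.na(f$U)))
  g <- buildSkeletonGraph(m)
  expect_equal(nrow(g@pixels), 0)
  expect_length(g@branches, 0)
})

test_that("propagated U is consistent with the nearest boundary point", {
  # 3 x 3 square: the center inherits the U of one of its boundary
  # neighbors (all equidistant; the marching-order tie-break picks one)
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  f <- propagateArrivalTimes(parameterizeBoundary(m))
  expect_true(f$U[3, 3] %in% 1:8)

  # convex masks: every interior pixel's arrival distance is within 1 px
  # of the exact distance to the true nearest boundary pixel (brute force;
  # the inherited source may be a tied alternative, so distances rather
  # than identities are compared)
  shapes <- list(
    diskMask(61, 30, 30, 20),
    rectMask(32, 64, 9, 24, 9, 56),
    { g <- expand.grid(r = 0:63, c = 0:63)
      matrix(((g$r - 32) * 0.8 + (g$c - 32) * 0.6)^2 / 625 +
             ((g$r - 32) * -0.6 + (g$c - 32) * 0.8)^2 / 144 <= 1, 64, 64) })
  for (m in shapes) {
    f <- propagateArrivalTimes(parameterizeBoundary(m))
    bidx <- which(f$boundary, arr.ind = TRUE)
    interior <- which(m & !f$boundary, arr.ind = TRUE)
    for (t in seq_len(nrow(interior))) {
      r <- interior[t, 1]; c <- interior[t, 2]
      dTrue <- min(sqrt((bidx[, 1] - r)^2 + (bidx[, 2] - c)^2))
      expect_lt(f$T[r, c] - dTrue, 1)
    }
  }
})

test_that("rectangle centerline lies on the medial line", {
  # 60 x 12 rectangle: rows 11..22 (y = 10..21), medial line y = 15.5
  m <- rectMask(32, 80, 11, 22, 11, 70)
  f <- propagateArrivalTimes(parameterizeBoundary(m))
  cl <- extractCenterline(f, 40)
  idx <- which(cl, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  span <- idx[idx[, 2] >= 23 & idx[, 2] <= 58, , drop = FALSE]
  expect_gt(nrow(span), 0)
  expect_true(all(abs((span[, 1] - 1) - 15.5) <= 1.5))
})

test_that("a disk's centerline collapses to its center", {
  m <- diskMask(61, 30, 30, 20)
  f <- propagateArrivalTimes(parameterizeBoundary(m))
  cl <- extractCenterline(f, 40)
  idx <- which(cl, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  expect_true(all(sqrt((idx[, 1] - 31)^2 + (idx[, 2] - 31)^2) <= 3))
})

test_that("raising the pruning threshold only removes centerline pixels", {
  masks <- list(diskMask(61, 30, 30, 20), rectMask(32, 80, 11, 22, 11, 70))
  fx <- oneFish(theta = 37, noise = 0)
  masks[[3]] <- segmentFrame(fx$img, fx$bg, 75)
  for (m in masks) {
    f <- propagateArrivalTimes(parameterizeBoundary(m))
    prev <- NULL
    for (tu in c(10, 20, 40, 70)) {
      cur <- which(extractCenterline(f, tu))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("thresholds at or above half the boundary empty the centerline", {
  m <- diskMask(61, 30, 30, 20)
  f <- propagateArrivalTimes(parameterizeBoundary(m))
  L <- max(f$boundaryLength)
  expect_equal(sum(extractCenterline(f, L / 2)), 0)
})

test_that("centerline rotates exactly with a 90-degree rotated capsule", {
  fish <- fishGeom()
  gtH <- data.frame(frame = 0L, fish_id = 1L, x = 120, y = 60,
                    theta_deg = 0, occluded = FALSE)
  gtV <- data.frame(frame = 0L, fish_id = 1L, x = 60, y = 120,
                    theta_deg = 90, occluded = FALSE)
  mH <- renderFrame(gtH, c(200, 120), fish, 0) < 130
  mV <- renderFrame(gtV, c(120, 200), fish, 0) < 130
  fH <- propagateArrivalTimes(parameterizeBoundary(mH))
  fV <- propagateArrivalTimes(parameterizeBoundary(mV))
  iH <- which(extractCenterline(fH, 15), arr.ind = TRUE)
  iV <- which(extractCenterline(fV, 15), arr.ind = TRUE)
  # (x, y) of the horizontal fish maps to (y, x) of the vertical one
  expect_setequal(paste(iH[, 2] - 1, iH[, 1] - 1),
                  paste(iV[, 1] - 1, iV[, 2] - 1))
})

test_that("fish capsule endpoints sit at the rendered cap centers", {
  fish <- fishGeom()
  gt1 <- data.frame(frame = 0L, fish_id = 1L, x = 120, y = 60,
                    theta_deg = 0, occluded = FALSE)
  mask <- renderFrame(gt1, c(200, 120), fish, 0) < 130
  g <- skeletonize(mask, tU = 8)
  ep <- g@endpoints
  expect_equal(nrow(ep), 2)
  core <- fish$length - fish$headHalfWidth - fish$tailHalfWidth
  caps <- rbind(c(120, 60), c(120 - core, 60))
  d <- sapply(seq_len(2), function(k)
    min(sqrt((ep[, 1] - caps[k, 1])^2 + (ep[, 2] - caps[k, 2])^2)))
  expect_true(all(d <= 3))
})

test_that("skeleton graphs count endpoints, junctions, branches", {
  m <- matrix(FALSE, 10, 30); m[5, 6:25] <- TRUE
  g <- buildSkeletonGraph(m)
  expect_equal(nrow(g@endpoints), 2)
  expect_equal(nrow(g@junctions), 0)
  expect_length(g@branches, 1)
  expect_equal(g@branches[[1]]$length, 20)

  # "Y": three arms meeting at one pixel (north + two diagonals, so only
  # the meeting pixel has three skeleton neighbors)
  m <- matrix(FALSE, 30, 30)
  m[5:15, 15] <- TRUE                         # north arm
  for (k in 1:10) m[15 + k, 15 - k] <- TRUE   # south-west arm
  for (k in 1:10) m[15 + k, 15 + k] <- TRUE   # south-east arm
  g <- buildSkeletonGraph(m)
  expect_equal(nrow(g@endpoints), 3)
  expect_equal(nrow(g@junctions), 1)
  expect_length(g@branches, 3)

  # crossed rectangles: an X-shaped mask through the full pipeline
  m <- matrix(FALSE, 80, 80)
  for (k in 0:59) {
    m[(10 + k) + (-3:3), 10 + k] <- TRUE
    m[(70 - k) + (-3:3), 10 + k] <- TRUE
  }
  g <- skeletonize(m, tU = 10)
  expect_equal(nrow(g@endpoints), 4)
  expect_gte(nrow(g@junctions), 1)
})
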