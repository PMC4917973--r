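test_that("generation is bit-exact under a fixed seed", {
  a <- makeBenchmark("easy", seed = 5, nFrames = 4)
  b <- makeBenchmark("easy", seed = 5, nFrames = 4)
  expect_identical(groundTruth(a), groundTruth(b))
  expect_identical(benchFrames(a), benchFrames(b))
  c2 <- makeBenchmark("easy", seed = 6, nFrames = 4)
  expect_false(identical(benchFrames(a)[[1]], benchFrames(c2)[[1]]))
})

test_that("profiles meet their construction contracts", {
  easy <- simulateTrajectories(10, 60, c(840, 630), seed = 3, avoid = TRUE)
  expect_equal(sum(easy$occluded), 0)

  dense <- makeBenchmark("dense", seed = 2, nFrames = 3)
  gt <- groundTruth(dense)
  expect_equal(length(unique(gt$fish_id)), 40)
  expect_true(all(table(gt$frame) == 40))
})

test_that("zero turn and jitter give straight segments between bounces", {
  mo <- list(speed = 5, jitter = 0, maxTurn = 0)
  gt <- simulateTrajectories(1, 40, c(400, 300), motion = mo, seed = 9)
  d <- sqrt(diff(gt$x)^2 + diff(gt$y)^2)
  expect_true(all(abs(d - 5) < 1e-9))
  # heading constant except at wall bounces
  turns <- abs(diff(gt$theta_deg))
  expect_true(all(turns %in% c(0) | turns > 1))
})

test_that("displacements and turns respect the declared envelopes", {
  gt <- simulateTrajectories(6, 80, c(700, 500), seed = 13, avoid = TRUE)
  for (i in 1:6) {
    g <- gt[gt$fish_id == i, ]
    d <- sqrt(diff(g$x)^2 + diff(g$y)^2)
    expect_true(all(d <= 60))   # pc_max envelope of the matched config
    dth <- abs(((diff(g$theta_deg) + 180) %% 360) - 180)
    expect_true(all(dth <= 180))
  }
})

test_that("engineered crossings produce occluded frames", {
  gt <- simulateTrajectories(4, 120, c(420, 420), seed = 7,
                             avoid = TRUE, crossings = 1)
  expect_gt(sum(gt$occluded), 0)
  # the occlusion involves the designated pair (fish 1 and 2)
  occ <- gt[gt$occluded, ]
  expect_true(all(occ$fish_id %in% c(1, 2)))
})

test_that("rendering matches the analytic capsule footprint", {
  fish <- fishGeom()
  gt1 <- data.frame(frame = 0L, fish_id = 1L, x = 70, y = 50,
                    theta_deg = 25, occluded = FALSE)
  img <- renderFrame(gt1, c(140, 100), fish, noiseSigma = 0)
  mask <- img < 130
  oracle <- capsuleFootprintOracle(gt1, c(140, 100), fish)
  # agreement away from the sampled-hull boundary band
  disagree <- which(mask != oracle, arr.ind = TRUE)
  expect_lte(nrow(disagree), ceiling(0.02 * sum(oracle)))
  # zero fish: pure background
  img0 <- renderFrame(gt1[0, ], c(60, 40), fish, noiseSigma = 0)
  expect_true(all(img0 == fish$backgroundGray))
})

test_that("the rendered head width matches the fish geometry", {
  fish <- fishGeom()
  gt1 <- data.frame(frame = 0L, fish_id = 1L, x = 80, y = 60,
                    theta_deg = 140, occluded = FALSE)
  img <- renderFrame(gt1, c(160, 120), fish, noiseSigma = 0)
  mask <- img < 130
  w <- measureEndpointWidth(c(x = 80, y = 60), mask)
  expect_lt(abs(w - 2 * fish$headHalfWidth), 2.1)
})

test_that("ground truth heading equals the rendered capsule axis", {
  fish <- fishGeom()
  for (th0 in c(0, 45, 133, 287)) {
    gt1 <- data.frame(frame = 0L, fish_id = 1L, x = 100, y = 80,
                      theta_deg = th0, occluded = FALSE)
    img <- renderFrame(gt1, c(200, 160), fish, noiseSigma = 0)
    mask <- img < 130
    idx <- which(mask, arr.ind = TRUE)
    # principal axis of the footprint
    xc <- idx[, 2] - 1 - mean(idx[, 2] - 1)
    yc <- idx[, 1] - 1 - mean(idx[, 1] - 1)
    ax <- atan2(2 * sum(xc * yc), sum(xc^2) - sum(yc^2)) / 2 * 180 / pi
    d <- abs(((ax - th0 + 90) %% 180) - 90)  # axis is orientation-only
    expect_lt(d, 2)
  }
})

test_that("fish centroids track the ground-truth midline", {
  bm <- makeBenchmark("easy", seed = 4, nFrames = 2)
  gt <- groundTruth(bm)
  g <- gt[gt$frame == 1, ]
  img <- benchFrames(bm)[[2]]
  mask <- img < 130
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  fish <- fishGeom()
  for (i in seq_len(nrow(g))) {
    # component under this fish's head
    comp <- lab[round(g$y[i]) + 1, round(g$x[i]) + 1]
    expect_gt(comp, 0)
    idx <- which(lab == comp, arr.ind = TRUE)
    cx <- mean(idx[, 2] - 1); cy <- mean(idx[, 1] - 1)
    # body midpoint from the truth
    seg <- fishHeadTracker:::.bodySegment(g$x[i], g$y[i], g$theta_deg[i], fish)
    mid <- (seg$A + seg$B) / 2
    expect_lt(sqrt((cx - mid[1])^2 + (cy - mid[2])^2), fish$length / 4)
  }
})
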