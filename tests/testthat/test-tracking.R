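test_that("position and direction changes follow their definitions", {
  expect_equal(positionChange(c(x = 1, y = 2), c(x = 1, y = 2)), 0)
  expect_equal(positionChange(c(x = 0, y = 0), c(x = 3, y = 4)), 5)
  expect_equal(positionChange(c(x = 10, y = 10), c(x = 10, y = 70)), 60)
  expect_equal(directionChange(10, 10), 0)
  expect_equal(directionChange(350, 10), 20)
  expect_equal(directionChange(0, 180), 180)
  # wrap symmetry over random pairs
  set.seed(2)
  a <- runif(50, 0, 360); b <- runif(50, 0, 360)
  expect_equal(directionChange(a, b), directionChange(b, a))
  expect_true(all(directionChange(a, b) <= 180))
})

test_that("association cost mixes normalized changes", {
  expect_equal(costValue(0, 0, 0.5, 60, 180), 0)
  for (w in c(0, 0.3, 0.5, 1))
    expect_equal(costValue(60, 180, w, 60, 180), 1)
  expect_equal(costValue(30, 90, 0.5, 60, 180), 0.5)
})

test_that("cost matrix gates on the occlusion distance", {
  prev <- data.frame(x = c(0, 1000), y = c(0, 1000), theta_deg = c(0, 0))
  curr <- data.frame(x = 5000, y = 5000, theta_deg = 0)
  A <- buildCostMatrix(prev, curr, 0.5, 60, 180, 300)
  expect_true(all(!is.finite(A)))

  prev <- data.frame(x = 0, y = 0, theta_deg = 0)
  curr <- data.frame(x = 3, y = 4, theta_deg = 0)
  A <- buildCostMatrix(prev, curr, 0.5, 60, 180, 300)
  expect_equal(A[1, 1], 0.5 * 5 / 60)

  prev <- data.frame(x = rep(0, 3), y = rep(0, 3), theta_deg = rep(0, 3))
  curr <- data.frame(x = c(10, 400, 20), y = 0, theta_deg = 0)
  A <- buildCostMatrix(prev, curr, 0.5, 60, 180, 300)
  expect_equal(is.finite(A[1, ]), c(TRUE, FALSE, TRUE))
})

test_that("assignment solves small matrices optimally", {
  sol <- solveAssignment(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2))
  expect_equal(sol$pairs, matrix(c(1L, 2L, 1L, 2L), 2, 2,
                                 dimnames = list(NULL, c("row", "col"))))
  expect_equal(sol$cost, 0.2)

  # forced off the greedy choice
  A <- matrix(c(0.2, 0.1, 0.3, Inf), 2, 2)
  sol <- solveAssignment(A)
  expect_equal(sol$cost, 0.4)
  expect_equal(sol$pairs[order(sol$pairs[, "row"]), "col"],
               c(2L, 1L), ignore_attr = TRUE)
})

test_that("assignment matches exhaustive search on random gated matrices", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    A <- matrix(runif(n * m), n, m)
    A[matrix(runif(n * m) < 0.2, n, m)] <- Inf
    sol <- solveAssignment(A)
    bf <- bruteAssignment(A)
    expect_equal(nrow(sol$pairs), bf$nPairs)
    expect_equal(sol$cost, bf$cost, tolerance = 1e-12)
    # never uses a gated entry
    if (nrow(sol$pairs)) expect_true(all(is.finite(A[sol$pairs])))
  }
})

test_that("initialization scans forward to the first frame with N detections", {
  d <- data.frame(frame = c(0, 0, 1, 1, 2, 2, 2),
                  x = 1:7, y = 1:7, theta_deg = 0)
  init <- initializeTracks(d, 3)
  expect_equal(init$startFrame, 2L)
  expect_equal(init$states$track_id, 1:3)

  d0 <- data.frame(frame = 0, x = 1:3, y = 1:3, theta_deg = 0)
  expect_equal(initializeTracks(d0, 3)$startFrame, 0L)

  expect_error(initializeTracks(d, 5), "initialization failure")
})

test_that("track stepping conserves N and propagates unmatched tracks", {
  prev <- data.frame(frame = 0L, track_id = 1:3,
                     x = c(0, 100, 200), y = c(0, 0, 0),
                     theta_deg = c(10, 20, 30), status = "detected")
  # m = n, detections at the previous positions: all matched at cost 0
  det <- data.frame(x = c(0, 100, 200), y = c(0, 0, 0),
                    theta_deg = c(10, 20, 30))
  cur <- stepTracks(prev, det, 1L, 0.5, 60, 180, 300)
  expect_equal(cur$status, rep("detected", 3))
  expect_equal(cur$x, prev$x)

  # m < n: missing fish propagated with unchanged state
  det2 <- data.frame(x = c(1, 101), y = c(0, 0), theta_deg = c(10, 20))
  cur2 <- stepTracks(prev, det2, 1L, 0.5, 60, 180, 300)
  expect_equal(sum(cur2$status == "propagated"), 1)
  p <- cur2[cur2$status == "propagated", ]
  expect_equal(p$x, 200); expect_equal(p$theta_deg, 30)

  # zero detections: everything propagated
  cur3 <- stepTracks(prev, det2[0, ], 1L, 0.5, 60, 180, 300)
  expect_equal(cur3$status, rep("propagated", 3))
  expect_equal(cur3[, c("x", "y", "theta_deg")],
               prev[, c("x", "y", "theta_deg")])

  # m > n: surplus detection dropped, still N states
  det4 <- data.frame(x = c(0, 100, 200, 50), y = c(0, 0, 0, 50),
                     theta_deg = c(10, 20, 30, 0))
  cur4 <- stepTracks(prev, det4, 1L, 0.5, 60, 180, 300)
  expect_equal(nrow(cur4), 3)
  expect_equal(sort(cur4$x), c(0, 100, 200))
})

test_that("a track propagated for k frames keeps an identical state", {
  d <- data.frame(frame = 0L, x = c(0, 100), y = c(0, 0),
                  theta_deg = c(0, 90))
  ts <- trackFish(d, nFrames = 6, N = 2, 0.5, 60, 180, 300)
  st <- trackStates(ts)
  expect_true(all(table(st$frame) == 2))
  for (id in 1:2) {
    s <- st[st$track_id == id & st$frame > 0, ]
    expect_equal(s$status, rep("propagated", 5))
    expect_equal(unique(s$x), st$x[st$track_id == id & st$frame == 0])
    expect_equal(unique(s$theta_deg),
                 st$theta_deg[st$track_id == id & st$frame == 0])
  }
})

test_that("detections with unavailable direction still associate", {
  prev <- data.frame(frame = 0L, track_id = 1:2, x = c(0, 100), y = c(0, 0),
                     theta_deg = c(0, 90), status = "detected")
  det <- data.frame(x = c(2, 98), y = c(0, 0), theta_deg = c(NA, 90))
  A <- buildCostMatrix(prev, det, 0.5, 60, 180, 300)
  # uninformative midpoint dc = dcMax/2 for the NA detection
  expect_equal(A[1, 1], 0.5 * 2 / 60 + 0.5 * 0.5)
  cur <- stepTracks(prev, det, 1L, 0.5, 60, 180, 300)
  expect_equal(cur$status, rep("detected", 2))
  # track keeps its previous direction when the detection has none
  expect_equal(cur$theta_deg[1], 0)
})
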