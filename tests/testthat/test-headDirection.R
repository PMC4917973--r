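test_that("Hessian responses vanish on a constant image", {
  img <- matrix(7, 64, 64)
  h <- hessianAt(img, 32, 32, 3)
  expect_equal(h$lxx, 0, tolerance = 1e-10)
  expect_equal(h$lxy, 0, tolerance = 1e-10)
  expect_equal(h$lyy, 0, tolerance = 1e-10)
  expect_equal(h$doh, 0, tolerance = 1e-10)
  sel <- selectScale(img, 32, 32, c(2, 3, 4))
  expect_true(sel$degenerate)
})

test_that("Hessian of a bilinear ramp isolates the mixed derivative", {
  xs <- 0:79
  img <- outer(xs, xs, function(y, x) x * y)  # rows = y, cols = x
  for (s in c(2, 4)) {
    h <- hessianAt(img, 40, 40, s)
    expect_equal(h$lxy, 1, tolerance = 1e-6)
    expect_equal(h$lxx, 0, tolerance = 1e-6)
    expect_equal(h$lyy, 0, tolerance = 1e-6)
  }
})

test_that("an isotropic Gaussian spot gives equal negative curvatures", {
  # bright spot of sd 4: smoothed curvature at the center is isotropic,
  # closed form L_xx = L_yy < 0, L_xy = 0
  xs <- 0:63
  img <- 100 * outer(xs, xs, function(y, x)
    exp(-((x - 32)^2 + (y - 32)^2) / (2 * 16)))
  h <- hessianAt(img, 32, 32, 4)
  expect_equal(h$lxy, 0, tolerance = 1e-6)
  expect_equal(h$lxx, h$lyy, tolerance = 1e-6)
  expect_lt(h$lxx, 0)
  expect_gt(h$doh, 0)
  # closed form: Gaussian o Gaussian composes sds, curvature at the peak
  # of amplitude A and combined variance v is -A' / v with the smoothed
  # amplitude A' = A * sb^2 / v
  v <- 16 + 16
  # discrete kernels vs the continuous closed form: sub-percent agreement
  expect_equal(h$lxx, -100 * 16 / v / v, tolerance = 0.02)
})

test_that("scale selection maximizes |DoH| with ties to the smaller scale", {
  xs <- 0:63
  img <- 100 * outer(xs, xs, function(y, x)
    exp(-((x - 32)^2 + (y - 32)^2) / (2 * 16)))
  scales <- c(2, 3, 4, 6, 8)
  sel <- selectScale(img, 32, 32, scales)
  dohs <- sapply(scales, function(s) abs(hessianAt(img, 32, 32, s)$doh))
  expect_equal(abs(sel$result$doh), max(dohs))
  expect_false(sel$degenerate)
  # single-scale list returns that scale
  expect_equal(selectScale(img, 32, 32, 5)$sHat, 5)
})

test_that("eigenvectors are orthonormal and ordered by magnitude", {
  set.seed(4)
  img <- matrix(runif(80 * 80, 0, 255), 80, 80)
  for (k in 1:10) {
    h <- hessianAt(img, sample(20:60, 1), sample(20:60, 1), 3)
    expect_gte(abs(h$lambda1), abs(h$lambda2))
    expect_equal(sum(h$alpha1^2), 1, tolerance = 1e-12)
    expect_equal(sum(h$alpha2^2), 1, tolerance = 1e-12)
    expect_equal(sum(h$alpha1 * h$alpha2), 0, tolerance = 1e-12)
  }
})

test_that("the sign ambiguity resolves along the skeleton hint", {
  h <- structure(list(lambda1 = -4, lambda2 = -1,
                      alpha1 = c(0, 1), alpha2 = c(-1, 0)),
                 class = "hessianResult")
  expect_equal(estimateTheta(h, hint = c(1, 0)), 0)
  expect_equal(estimateTheta(h, hint = c(-1, 0)), 180)
  # isotropic patch: direction unavailable, never a numeric angle
  hIso <- structure(list(lambda1 = -1, lambda2 = -1,
                         alpha1 = c(1, 0), alpha2 = c(0, 1)),
                    class = "hessianResult")
  expect_true(is.na(estimateTheta(hIso, c(1, 0), anisotropyMin = 1.2)))
  hFlat <- structure(list(lambda1 = 0, lambda2 = 0,
                          alpha1 = c(1, 0), alpha2 = c(0, 1)),
                     class = "hessianResult")
  expect_true(is.na(estimateTheta(hFlat, c(1, 0))))
})

test_that("estimated direction tracks the true heading and its rotations", {
  fish <- fishGeom()
  cfg <- fishTrackConfig("synthetic", nFish = 1)
  estOne <- function(theta) {
    fx <- oneFish(x = 110, y = 90, theta = theta, noise = 0,
                  arena = c(220, 180))
    d <- detectFrame(fx$img, fx$bg, cfg, 0L)
    expect_equal(nrow(d), 1)
    d$theta_deg
  }
  t0 <- estOne(0)
  expect_lt(directionChange(t0, 0), 5)
  t90 <- estOne(90)
  expect_lt(directionChange(t90, t0 + 90), 3)
  t37 <- estOne(37)
  t127 <- estOne(127)
  expect_lt(directionChange(t127, t37 + 90), 3)
})

test_that("direction errors stay small across random headings", {
  set.seed(31)
  cfg <- fishTrackConfig("synthetic", nFish = 1)
  errs <- numeric(0)
  for (k in 1:25) {
    th0 <- runif(1, 0, 360)
    fx <- oneFish(theta = th0, noise = 2, seed = k)
    d <- detectFrame(fx$img, fx$bg, cfg, 0L)
    if (nrow(d) == 1 && !is.na(d$theta_deg))
      errs <- c(errs, directionChange(d$theta_deg, th0))
  }
  expect_gte(length(errs), 20)
  expect_lt(mean(errs), 10)
})
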