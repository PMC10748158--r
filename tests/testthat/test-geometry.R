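test_that("depth lookup scales raw units and signals invalid depth", {
  d <- matrix(0L, 120, 160)
  d[61, 81] <- 2000L           # pixel (u=80, v=60)
  d[61, 82] <- 65535L
  fr <- makeFrame(d, id = "dl")
  expect_equal(depthAt(fr, 80, 60), 2.0)
  expect_equal(depthAt(fr, 81, 60), 65.535)
  expect_true(is.na(depthAt(fr, 0, 0)))          # raw 0 -> NA, not 0 m
  expect_error(depthAt(fr, 160, 0), "out of bounds")
  ## float keypoints are rounded half-up to the nearest pixel centre
  expect_equal(depthAt(fr, 79.5, 59.6), 2.0)
})

test_that("3x3 median fallback patches an invalid centre pixel when enabled", {
  d <- matrix(1500L, 120, 160)
  d[61, 81] <- 0L
  fr <- makeFrame(d, id = "mf")
  expect_true(is.na(depthAt(fr, 80, 60)))
  expect_equal(depthAt(fr, 80, 60, medianFallback = TRUE), 1.5)
})

test_that("deprojection matches hand pinhole algebra", {
  intr <- intr600()
  expect_equal(deprojectPixel(320, 240, 2, intr)[1, ],
               c(X = 0, Y = 0, Z = 2))
  expect_equal(deprojectPixel(920, 240, 2, intr)[1, ],
               c(X = 2, Y = 0, Z = 2))   # X = (u-cx)/fx * Z
  expect_error(deprojectPixel(320, 240, 0, intr), "depth")
})

test_that("Brown-Conrady distortion round-trips through the iterative inverse", {
  intr <- cameraIntrinsics(fx = 600, fy = 600,
                           hfov = 2 * atan(640 / 1200) * 180 / pi,
                           distortionModel = "brown_conrady",
                           distortionCoeffs = c(0.01, -0.003, 1e-4, -2e-4, 0))
  set.seed(2)
  u <- runif(1000, 0, 639); v <- runif(1000, 0, 479); z <- runif(1000, 0.5, 6)
  P <- deprojectPixel(u, v, z, intr)
  px <- projectPoint(P, intr)
  expect_lt(max(abs(px[, 1] - u)), 1e-4)
  expect_lt(max(abs(px[, 2] - v)), 1e-4)
  back <- deprojectPixel(px[, 1], px[, 2], px[, 3] * intr@depthScale, intr)
  expect_lt(max(abs(back - P)), 1e-6)
})

test_that("nose-to-nose distance matches an independent norm computation", {
  intr <- intr600()
  expect_equal(noseToNose(c(320, 240, 2), c(320, 240, 2), intr), 0)
  ## P0 = (0,0,1), P1 = (3,4,1) via pixels: a 3-4-5(+0) construction
  m <- noseToNose(c(320, 240, 1), c(320 + 600 * 3, 240 + 600 * 4, 1), intr)
  expect_equal(m, 5.0, tolerance = 1e-12)
  skipped <- noseToNose(c(320, 240, NA), c(320, 240, 2), intr)
  expect_true(is.na(skipped))
  expect_equal(attr(skipped, "reason"), "invalid depth")

  set.seed(3)
  for (i in 1:200) {
    p0 <- c(runif(1, 0, 639), runif(1, 0, 479), runif(1, 0.5, 6))
    p1 <- c(runif(1, 0, 639), runif(1, 0, 479), runif(1, 0.5, 6))
    ## independent component-wise oracle
    q0 <- c((p0[1] - 320) / 600 * p0[3], (p0[2] - 240) / 600 * p0[3], p0[3])
    q1 <- c((p1[1] - 320) / 600 * p1[3], (p1[2] - 240) / 600 * p1[3], p1[3])
    expect_equal(noseToNose(p0, p1, intr),
                 sqrt(sum((q0 - q1)^2)), tolerance = 1e-9)
  }
})

test_that("nose-to-nose distance satisfies the metric axioms", {
  intr <- busIntrinsics()
  set.seed(4)
  for (i in 1:100) {
    ps <- lapply(1:3, function(j)
      c(runif(1, 0, 639), runif(1, 0, 479), runif(1, 0.5, 6)))
    d01 <- noseToNose(ps[[1]], ps[[2]], intr)
    d10 <- noseToNose(ps[[2]], ps[[1]], intr)
    d02 <- noseToNose(ps[[1]], ps[[3]], intr)
    d12 <- noseToNose(ps[[2]], ps[[3]], intr)
    expect_identical(d01, d10)                       # symmetry
    expect_lte(d02, d01 + d12 + 1e-12)               # triangle inequality
    expect_gt(d01, 0)                                # distinct a.s.
    expect_equal(noseToNose(ps[[1]], ps[[1]], intr), 0)
  }
})

test_that("distance is stably bounded under depth perturbations", {
  intr <- busIntrinsics()
  set.seed(5)
  for (i in 1:100) {
    p0 <- c(runif(1, 0, 639), runif(1, 0, 479), runif(1, 0.5, 6))
    p1 <- c(runif(1, 0, 639), runif(1, 0, 479), runif(1, 0.5, 6))
    dd <- runif(1, -0.05, 0.05)
    m0 <- noseToNose(p0, p1, intr)
    m1 <- noseToNose(p0 + c(0, 0, dd), p1, intr)
    bound <- (1 + sqrt((p0[1] - intr@cx)^2 + (p0[2] - intr@cy)^2) /
                min(intr@fx, intr@fy)) * abs(dd)
    expect_lte(abs(m1 - m0), bound + 1e-12)
  }
})

test_that("measured distances equal ground truth on exact inputs", {
  ## geometry-chain check on exact (u, v, depth) floats: the 16-bit raw
  ## frame path is quantised to the depth unit and checked separately
  cfg <- smallScenario(seed = 6, arrivalRate = 2, dwellTime = 5,
                       depthNoiseFrac = 0, detectionDropout = 0,
                       duplicateFrameRate = 0)
  day <- simulateDay(cfg, duration = 10)
  intr <- cfg@intrinsics
  checkedFrames <- 0L
  for (k in seq_along(day$frames)) {
    g <- day$truth$frames[[k]]$passengers
    if (nrow(g) < 2) next
    dm <- day$truth$frames[[k]]$distances
    for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
      m <- noseToNose(c(g$u[i], g$v[i], g$camZ[i]),
                      c(g$u[j], g$v[j], g$camZ[j]), intr)
      expect_equal(m, dm[g$id[i], g$id[j]], tolerance = 1e-6)
    }
    checkedFrames <- checkedFrames + 1L
  }
  expect_gt(checkedFrames, 10L)

  ## raw-frame path: within the quantisation bound of the depth unit
  pre <- preprocessFrames(day$frames, intr)
  fds <- measureFrames(pre$frames, intr)
  for (fd in fds) {
    if (nrow(fd$pairs) == 0) next
    k <- match(fd$frameId, vapply(day$frames, frameId, character(1)))
    dm <- day$truth$frames[[k]]$distances
    for (r in seq_len(nrow(fd$pairs)))
      expect_equal(fd$pairs$m[r], dm[fd$pairs$id0[r], fd$pairs$id1[r]],
                   tolerance = 5e-3)
  }
})

test_that("polar bearing is linear in the pixel column", {
  intr <- busIntrinsics()
  expect_equal(polarOf(0, 2, intr)[1, "theta"], 0, ignore_attr = TRUE)
  expect_equal(polarOf(320, 2, intr)[1, "theta"], 37.0, ignore_attr = TRUE)
  expect_equal(polarOf(640, 2, intr)[1, "theta"], 74, ignore_attr = TRUE)
  expect_error(polarOf(-1, 2, intr), "out of")
  expect_error(polarOf(320, 0, intr), "D must be")
})
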