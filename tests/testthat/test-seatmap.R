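test_that("distance-plane reduction drops the vertical component", {
  intr <- busIntrinsics()
  ## on the optical axis at Z = 2: r = 2 and the centred bearing is 0
  dp <- toDistancePlane(intr@cx, intr@cy, 2, intr)
  expect_equal(dp[1, ], c(x = 0, y = 2), tolerance = 1e-12)
  ## deprojected (X, Y, Z) = (1, 1, 2): r = sqrt(X^2 + Z^2) = sqrt(5)
  u <- intr@cx + intr@fx * (1 / 2); v <- intr@cy + intr@fy * (1 / 2)
  dp <- toDistancePlane(u, v, 2, intr)
  expect_equal(sqrt(sum(dp^2)), sqrt(5), tolerance = 1e-12)
  ## NA depth propagates as a skipped row
  dp <- toDistancePlane(c(intr@cx, 10), c(intr@cy, 10), c(2, NA), intr)
  expect_true(all(is.na(dp[2, ])))
})

test_that("a homography is recovered exactly from clean correspondences", {
  Hstar <- rbind(c(900, -40, 1100), c(25, 1010, -380), c(2e-4, -3e-4, 1))
  set.seed(21)
  src <- cbind(runif(15, -2, 2), runif(15, 1, 6))
  dst <- toPlan(src, Hstar)
  H <- estimateHomography(src, dst, seed = 5)
  expect_lt(max(abs(toPlan(src, H) - dst)), 1e-6)
  expect_true(all(inlierMask(H)))
  expect_lt(H@medianResidual, 1e-12)
})

test_that("LMedS rejects grossly corrupted correspondences", {
  Hstar <- rbind(c(950, 10, 1000), c(-15, 980, -420), c(1e-4, 2e-4, 1))
  set.seed(22)
  src <- cbind(runif(15, -2, 2), runif(15, 1, 6))
  dst <- toPlan(src, Hstar)
  bad <- c(2, 7, 13)
  dst[bad, ] <- dst[bad, ] + cbind(runif(3, 800, 2000), runif(3, 800, 2000))
  H <- estimateHomography(src, dst, seed = 5)
  expect_equal(which(!inlierMask(H)), bad)
  clean <- setdiff(1:15, bad)
  expect_lt(max(abs(toPlan(src[clean, ], H) - dst[clean, ])), 1e-6)
})

test_that("identity correspondences give the identity transform", {
  set.seed(23)
  pts <- cbind(runif(10, -3, 3), runif(10, -3, 3))
  H <- estimateHomography(pts, pts, seed = 1)
  expect_equal(homographyMatrix(H), diag(3), tolerance = 1e-9)
})

test_that("estimation is deterministic for a fixed seed", {
  set.seed(24)
  src <- cbind(runif(30, -2, 2), runif(30, 1, 6))
  Hstar <- rbind(c(1000, 0, 500), c(0, 1000, 0), c(0, 1e-4, 1))
  dst <- toPlan(src, Hstar) + matrix(rnorm(60, 0, 5), ncol = 2)
  h1 <- estimateHomography(src, dst, seed = 9)
  h2 <- estimateHomography(src, dst, seed = 9)
  expect_identical(homographyMatrix(h1), homographyMatrix(h2))
})

test_that("estimation is equivariant under similarity transforms of the plan", {
  Hstar <- rbind(c(900, -40, 1100), c(25, 1010, -380), c(2e-4, -3e-4, 1))
  set.seed(25)
  src <- cbind(runif(15, -2, 2), runif(15, 1, 6))
  dst <- toPlan(src, Hstar)
  a <- pi / 7; s <- 1.3
  Sim <- rbind(c(s * cos(a), -s * sin(a), 200),
               c(s * sin(a),  s * cos(a), -80), c(0, 0, 1))
  H1 <- estimateHomography(src, dst, seed = 2)
  H2 <- estimateHomography(src, t(Sim %*% t(cbind(dst, 1)))[, 1:2], seed = 2)
  composed <- Sim %*% homographyMatrix(H1)
  composed <- composed / composed[3, 3]
  expect_equal(homographyMatrix(H2), composed, tolerance = 1e-6)
})

test_that("degenerate correspondence sets are refused", {
  src <- cbind(seq(0, 3, length.out = 6), 2 * seq(0, 3, length.out = 6))
  dst <- src * 100   # all collinear
  expect_error(estimateHomography(src, dst, seed = 1), "degenerate")
  expect_error(estimateHomography(src[1:3, ], dst[1:3, ], seed = 1), ">= 4")
})

test_that("plan transforms match direct homogeneous algebra", {
  expect_equal(toPlan(c(1, 2), diag(3)), cbind(x = 1, y = 2))
  Htr <- rbind(c(1, 0, 50), c(0, 1, -20), c(0, 0, 1))
  expect_equal(toPlan(c(1, 2), Htr), cbind(x = 51, y = -18))
  set.seed(26)
  H <- rbind(c(800, 30, 900), c(-20, 1050, 100), c(3e-4, -2e-4, 1))
  pts <- cbind(runif(100, -3, 3), runif(100, 0.5, 7))
  got <- toPlan(pts, H)
  for (i in 1:100) {
    hv <- H %*% c(pts[i, ], 1)
    expect_equal(unname(got[i, ]), c(hv[1] / hv[3], hv[2] / hv[3]),
                 tolerance = 1e-9)
  }
  Hinf <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0))   # w = x
  expect_error(toPlan(c(0, 1), Hinf), "infinity")
})

test_that("seat allocation agrees with a ray-casting oracle", {
  plan <- busSeatPlan()
  expect_equal(allocateSeat(seatAnchors(plan, "C4")[, c("x", "y")], plan),
               "C4")
  expect_equal(allocateSeat(c(-500, -500), plan), "unallocated")
  ## excluded seats are never returned
  expect_equal(allocateSeat(seatAnchors(plan, "F1")[, c("x", "y")], plan),
               "unallocated")

  set.seed(27)
  pts <- cbind(runif(1000, -200, 2600), runif(1000, -200, 5800))
  got <- allocateSeat(pts, plan)
  labs <- sort(setdiff(names(seatPolygons(plan)), excludedSeats(plan)))
  polys <- c(seatPolygons(plan)[labs], list(aisle = aislePolygon(plan)))
  oracle <- apply(pts, 1, function(p) {
    for (nm in names(polys))
      if (rayCastInside(p[1], p[2], polys[[nm]])) return(nm)
    "unallocated"
  })
  expect_equal(got, oracle)
})

test_that("overlapping plan polygons are rejected at load time", {
  seats <- list(X1 = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                X2 = cbind(c(50, 150, 150, 50), c(50, 50, 150, 150)))
  aisle <- cbind(c(500, 600, 600, 500), c(0, 0, 100, 100))
  expect_error(seatPlan(seats, aisle), "overlapping")
})

test_that("occupancy series recovers percent occupied and merged events", {
  times <- as.POSIXct("2021-05-10 08:00:00", tz = "UTC") + (0:3) * 5
  alloc <- data.frame(frameId = c("f1", "f2", "f3", "f4", "f2"),
                      timestamp = times[c(1, 2, 3, 4, 2)],
                      detectionId = c("a", "a", "a", "a", "b"),
                      seat = c("C4", "C4", "C4", "C4", "B1"),
                      stringsAsFactors = FALSE)
  occ <- occupancySeries(alloc, times)
  expect_equal(occ$percent$percent[occ$percent$seat == "C4"], 100)
  expect_equal(occ$percent$percent[occ$percent$seat == "B1"], 25)
  ## a single missing frame does not split an event
  alloc2 <- alloc[alloc$seat == "C4" & alloc$frameId != "f2", ]
  occ2 <- occupancySeries(alloc2, times)
  ev <- occ2$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, times[1])
  expect_equal(ev$end, times[4])
  ## but a two-frame gap does, with the default tolerance
  alloc3 <- alloc[alloc$seat == "C4" & !alloc$frameId %in% c("f2", "f3"), ]
  expect_equal(nrow(occupancySeries(alloc3, times)$events), 2L)
  expect_error(occupancySeries(alloc, rev(times)), "order")
})

test_that("sit and leave times are recovered within one frame interval", {
  cfg <- smallScenario(seed = 33, arrivalRate = 1, dwellTime = 4,
                       depthNoiseFrac = 0, detectionDropout = 0,
                       duplicateFrameRate = 0)
  day <- simulateDay(cfg, duration = 30)
  ## border margin proportional to the reduced test image (30 px is the
  ## full-VGA setting and would crop the nearest window seats here)
  pre <- preprocessFrames(day$frames, cfg@intrinsics, borderRadius = 8)
  corr <- referenceCorrespondences(cfg)
  src <- toDistancePlane(corr$u, corr$v, corr$depth_m, cfg@intrinsics)
  H <- estimateHomography(src, cbind(corr$plan_x_mm, corr$plan_y_mm),
                          seed = cfg@seed)
  alloc <- allocateDetections(pre$frames, cfg@intrinsics, H, cfg@seatPlan)
  times <- as.POSIXct(vapply(pre$frames,
                                      function(f) as.numeric(f@timestamp),
                                      numeric(1)),
                               origin = "1970-01-01", tz = "UTC")
  occ <- occupancySeries(alloc, times)
  t0 <- times[1]
  lastT <- 30 * 60 - 5
  ## every stay that spans at least one frame time is covered by a
  ## recovered event whose ends are within one frame interval
  for (i in seq_len(nrow(day$truth$occupants))) {
    o <- day$truth$occupants[i, ]
    firstFrame <- ceiling(o$tSit / 5) * 5
    if (firstFrame >= o$tLeave || firstFrame > lastT) next  # never sampled
    ev <- occ$events[occ$events$seat == o$seat, , drop = FALSE]
    sitT <- as.numeric(ev$start - t0, units = "secs")
    leaveT <- as.numeric(ev$end - t0, units = "secs")
    hit <- which(sitT <= o$tSit + 5 + 1e-9 &
                 leaveT >= min(o$tLeave, lastT) - 5 - 1e-9)
    expect_gte(length(hit), 1L)
  }
  ## global tightness: recovered occupied frames match ground truth exactly
  gtFrames <- table(unlist(lapply(day$truth$frames,
                                  function(g) unique(g$passengers$seat))))
  expect_setequal(occ$percent$seat, names(gtFrames))
  for (seat in names(gtFrames))
    expect_equal(occ$percent$occupiedFrames[occ$percent$seat == seat],
                 unname(gtFrames[seat]), ignore_attr = TRUE)
})

test_that("ground-truth seats are recovered end to end", {
  ## noiseless scenes
  cfg0 <- scenarioConfig(seed = 35, depthNoiseFrac = 0, detectionDropout = 0,
                         duplicateFrameRate = 0, arrivalRate = 1,
                         dwellTime = 6)
  day0 <- simulateDay(cfg0, duration = 10)
  pre0 <- preprocessFrames(day0$frames, cfg0@intrinsics)
  corr <- referenceCorrespondences(cfg0)
  src <- toDistancePlane(corr$u, corr$v, corr$depth_m, cfg0@intrinsics)
  H0 <- estimateHomography(src, cbind(corr$plan_x_mm, corr$plan_y_mm),
                           seed = cfg0@seed)
  a0 <- allocateDetections(pre0$frames, cfg0@intrinsics, H0, cfg0@seatPlan)
  gt <- gtSeatLookup(day0)
  expect_gt(nrow(a0), 100L)
  expect_gte(mean(a0$seat == gt[a0$detectionId]), 0.99)

  ## default noise
  cfg1 <- scenarioConfig(seed = 36, arrivalRate = 1, dwellTime = 6,
                         duplicateFrameRate = 0)
  day1 <- simulateDay(cfg1, duration = 10)
  pre1 <- preprocessFrames(day1$frames, cfg1@intrinsics)
  a1 <- allocateDetections(pre1$frames, cfg1@intrinsics, H0, cfg1@seatPlan)
  gt1 <- gtSeatLookup(day1)
  expect_gte(mean(a1$seat == gt1[a1$detectionId]), 0.90)
})
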