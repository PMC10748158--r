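## Independent oracles and fixture builders. Oracles deliberately avoid the
## package's own code paths.

## Even-odd ray-casting point-in-polygon test (horizontal ray to +inf).
## Intended for points in general position (not on edges).
rayCastInside <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

## Truncated Poisson pmf on 0..cap: the stationary law of the loss process
## with offered load a = arrivalRate * dwellTime.
truncPoisPMF <- function(a, cap) {
  p <- dpois(0:cap, a)
  p / sum(p)
}

## Small-image intrinsics for fast simulation; same fields of view as the
## full camera so the scene geometry is unchanged.
smallIntrinsics <- function() cameraIntrinsics(width = 160L, height = 120L)

## Intrinsics with round focal lengths for hand-computed examples.
intr600 <- function() {
  cameraIntrinsics(width = 640L, height = 480L, fx = 600, fy = 600,
                   cx = 320, cy = 240,
                   hfov = 2 * atan(640 / 1200) * 180 / pi,
                   vfov = 2 * atan(480 / 1200) * 180 / pi)
}

## Bare detection with the nose at (u, v).
makeDetection <- function(u, v, conf = 0.9, id = "d1") {
  kp <- matrix(0, 17L, 3L, dimnames = list(NULL, c("u", "v", "confidence")))
  kp[1L, ] <- c(u, v, conf)
  new("DetectionRecord", keypoints = kp, detectionId = id)
}

## Frame with a constant (or given) raw depth matrix.
makeFrame <- function(depth, detections = list(), S = 0.001,
                      id = "f1", rotated = TRUE) {
  if (length(depth) == 1L) depth <- matrix(as.integer(depth), 480L, 640L)
  new("FrameRecord", frameId = id,
      timestamp = as.POSIXct("2021-05-10 08:00:00", tz = "UTC"),
      depth = depth, depthScale = S, detections = detections,
      rotated = rotated)
}

## Fast scenario for tests that only need the process / GT structure.
smallScenario <- function(...) {
  scenarioConfig(intrinsics = smallIntrinsics(), ...)
}

## A two-seat plan whose anchors are exactly `gap` metres apart (across).
twoSeatPlan <- function(gap = 0.5) {
  g <- gap * 1000
  seats <- list(
    S1 = cbind(x = c(800, 1100, 1100, 800), y = c(2000, 2000, 2400, 2400)),
    S2 = cbind(x = c(800, 1100, 1100, 800) + g, y = c(2000, 2000, 2400, 2400)))
  aisle <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  seatPlan(seats, aisle)
}

## Ground-truth seat per detection id from a simulated day.
gtSeatLookup <- function(day) {
  setNames(day$truth$occupants$seat, day$truth$occupants$id)
}

## Per-frame occupancy counts from ground truth.
gtOccupancy <- function(day) {
  vapply(day$truth$frames, function(g) nrow(g$passengers), integer(1))
}
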