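## Synthetic bus-scene generator: ground-truthed depth frames + keypoint
## records standing in for real footage (which is not publishable).

## Seated-pose keypoint offsets relative to the nose, bus frame, metres:
## columns are (across, along, up) for a passenger facing the front (-y).
## COCO order: nose, eyes, ears, shoulders, elbows, wrists, hips, knees,
## ankles (left then right).
.POSE_OFFSETS <- matrix(c(
   0.00,  0.00,  0.00,   # nose
  -0.03,  0.02,  0.03,   # left eye
   0.03,  0.02,  0.03,   # right eye
  -0.07,  0.05,  0.02,   # left ear
   0.07,  0.05,  0.02,   # right ear
  -0.18,  0.05, -0.25,   # left shoulder
   0.18,  0.05, -0.25,   # right shoulder
  -0.22,  0.02, -0.50,   # left elbow
   0.22,  0.02, -0.50,   # right elbow
  -0.20, -0.10, -0.65,   # left wrist
   0.20, -0.10, -0.65,   # right wrist
  -0.15,  0.05, -0.75,   # left hip
   0.15,  0.05, -0.75,   # right hip
  -0.15, -0.30, -0.85,   # left knee
   0.15, -0.30, -0.85,   # right knee
  -0.15, -0.25, -1.15,   # left ankle
   0.15, -0.25, -1.15    # right ankle
), ncol = 3L, byrow = TRUE)

.COCO_NAMES <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
                 "left_shoulder", "right_shoulder", "left_elbow",
                 "right_elbow", "left_wrist", "right_wrist", "left_hip",
                 "right_hip", "left_knee", "right_knee", "left_ankle",
                 "right_ankle")

.BASE_TIME <- as.POSIXct("2021-05-10 07:00:00", tz = "UTC")

## Truncated Gaussian multiplicative depth noise: draws clipped at +/- 3 sd,
## reflecting a bounded device error specification.
.depthNoise <- function(n, frac) {
  if (frac == 0) return(rep(1, n))
  z <- rnorm(n, 0, frac)
  hi <- 3 * frac
  z[z > hi] <- hi
  z[z < -hi] <- -hi
  1 + z
}

## Static interior geometry in bus-frame metres: room box + coarse seat
## boxes (cushions and backrests). Analysis only reads depth at keypoint
## pixels, so coarse fidelity suffices.
.interiorBoxes <- function(config) {
  plan <- config@seatPlan
  boxes <- list()
  for (nm in names(seatPolygons(plan))) {
    p <- seatPolygons(plan)[[nm]] / 1000
    x0 <- min(p[, 1]); x1 <- max(p[, 1])
    y0 <- min(p[, 2]); y1 <- max(p[, 2])
    boxes[[paste0(nm, ".cushion")]] <- c(x0, y0, 0, x1, y1, 0.45)
    boxes[[paste0(nm, ".back")]] <- c(x0, y1 - 0.1, 0, x1, y1, 1.05)
  }
  boxes
}

## Z-depth (metres) of the static scene for every pixel, camera model of
## `config`. Room: floor z=0, ceiling 2.3 m, walls at x=0/2.4 and y=-0.2/6.
.renderBackground <- function(config) {
  intr <- config@intrinsics
  w <- intr@width; h <- intr@height
  u <- rep(0:(w - 1L), each = h)     # column-major over (v, u)
  v <- rep(0:(h - 1L), times = w)
  dcam <- cbind((u - intr@cx) / intr@fx, (v - intr@cy) / intr@fy, 1)
  R <- .cameraRotation(config)
  dbus <- dcam %*% R                  # rows: ray directions in bus frame
  C <- config@cameraPosition
  big <- Inf
  ## axis-aligned planes: list(axis index, plane coordinate)
  planes <- list(c(3, 0), c(3, 2.3), c(1, 0), c(1, 2.4), c(2, -0.2), c(2, 6))
  s <- rep(big, length(u))
  for (pl in planes) {
    d <- dbus[, pl[1]]
    si <- (pl[2] - C[pl[1]]) / d
    si[!is.finite(si) | si <= 1e-9] <- big
    s <- pmin(s, si)
  }
  for (b in .interiorBoxes(config)) {
    t0 <- rep(-big, length(u)); t1 <- rep(big, length(u))
    for (ax in 1:3) {
      d <- dbus[, ax]
      lo <- (b[ax] - C[ax]) / d
      hi <- (b[ax + 3] - C[ax]) / d
      sw <- d < 0
      tmp <- lo[sw]; lo[sw] <- hi[sw]; hi[sw] <- tmp
      t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
    }
    hit <- t0 <= t1 & t0 > 1e-9
    s[hit] <- pmin(s[hit], t0[hit])
  }
  matrix(s, nrow = h, ncol = w)   # s equals camera Z-depth for these rays
}

## Sample one seat among `free` labels, proportional to weights.
.chooseSeat <- function(free, weights) {
  w <- weights[free]
  free[sample.int(length(free), 1L, prob = w / sum(w))]
}

## Simulate the boarding/alighting process: Poisson arrivals at
## `arrivalRate`/min, exponential dwell (mean `dwellTime` min), blocked when
## all choosable seats are taken; initial state drawn from the stationary
## truncated Poisson so the sampled day is stationary from the first frame.
.simulateOccupants <- function(config, horizon) {
  w <- config@preferenceWeights
  eff <- names(w)[w > 0]
  cap <- length(eff)
  a <- config@arrivalRate * config@dwellTime
  meanDwell <- config@dwellTime * 60
  occ <- data.frame(id = character(), seat = character(),
                    tSit = numeric(), tLeave = numeric(),
                    stringsAsFactors = FALSE)
  counter <- 0L
  addOccupant <- function(seat, tSit, dwell) {
    counter <<- counter + 1L
    occ[nrow(occ) + 1L, ] <<- list(sprintf("p%04d", counter), seat,
                                   tSit, tSit + dwell)
  }
  n0 <- if (config@arrivalRate > 0) {
    lp <- dpois(0:cap, a, log = TRUE)    # log-space: stable at heavy load
    p <- exp(lp - max(lp))
    sample.int(cap + 1L, 1L, prob = p / sum(p)) - 1L
  } else 0L
  for (i in seq_len(n0)) {
    free <- setdiff(eff, occ$seat[occ$tLeave > 0])
    addOccupant(.chooseSeat(free, w), 0, rexp(1, 1 / meanDwell))
  }
  if (config@arrivalRate > 0) {
    t <- 0
    repeat {
      t <- t + rexp(1, config@arrivalRate / 60)
      if (t > horizon) break
      free <- setdiff(eff, occ$seat[occ$tSit <= t & occ$tLeave > t])
      if (length(free) == 0L) next   # blocked arrival (bus full)
      addOccupant(.chooseSeat(free, w), t, rexp(1, 1 / meanDwell))
    }
  }
  occ
}

#' Simulate a day of bus-service depth capture
#'
#' Generates a timestamp-ordered stream of depth frames with per-passenger
#' COCO keypoint detections, together with the ground truth the analysis is
#' later checked against: per-frame nose positions in bus and camera frames,
#' projected pixels, and the true pairwise nose-to-nose distance matrix.
#' Boarding and alighting follow a memoryless (Poisson arrival, exponential
#' dwell) process truncated at the choosable-seat count; seat choice is a
#' categorical draw over free seats proportional to the scenario's
#' preference weights. Nose positions are jittered isotropically (sd 3 cm
#' by default) around the seat anchor each frame. Identical seed and
#' configuration give byte-identical output.
#'
#' Frames are emitted in captured orientation: the camera is mounted
#' upside-down, so depth matrices and keypoints are rotated 180 degrees
#' relative to the analysis orientation until \code{\link{rotate180}} (or
#' \code{\link{preprocessFrames}}) is applied. Ground-truth pixels are
#' given in analysis orientation.
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param duration simulated duration in minutes
#' @param frameInterval capture cadence in seconds (default one frame every
#'   5 s)
#' @return a list with elements \code{frames} (list of
#'   \linkS4class{FrameRecord}, including any injected duplicates) and
#'   \code{truth}, itself a list with per-frame ground truth
#'   (\code{$frames}: for each frame a list with \code{passengers}
#'   data.frame and \code{distances} matrix), the \code{occupants} table
#'   (id, seat, tSit, tLeave seconds), indices of injected duplicate frames
#'   (\code{duplicates}), and the frame times
#' @examples
#' day <- simulateDay(scenarioConfig(seed = 7), duration = 2)
#' length(day$frames)
#' day$frames[[1]]
#' @export
simulateDay <- function(config, duration, frameInterval = 5) {
  stopifnot(is(config, "ScenarioConfig"))
  if (duration <= 0) .stopf("duration must be > 0 minutes")
  if (frameInterval <= 0) .stopf("frameInterval must be > 0 seconds")
  validObject(config)
  intr <- config@intrinsics
  w <- intr@width; h <- intr@height; S <- intr@depthScale

  anchors <- seatAnchors(config@seatPlan)
  anchors3 <- cbind(anchors$x / 1000, anchors$y / 1000, config@seatAnchorHeight)
  rownames(anchors3) <- anchors$seat
  eff <- names(config@preferenceWeights)[config@preferenceWeights > 0]
  cam <- .busToCamera(anchors3[eff, , drop = FALSE], config)
  visible <- cam[, 3] > 0
  if (any(visible)) {
    px <- projectPoint(cam[visible, , drop = FALSE], intr)
    visible[visible] <- px[, 1] >= 0 & px[, 1] < w & px[, 2] >= 0 & px[, 2] < h
  }
  if (!any(visible))
    .stopf(paste0("camera pose places zero seats in view ",
                  "(position %.2f, %.2f, %.2f m; pitch %.1f deg)"),
           config@cameraPosition[1], config@cameraPosition[2],
           config@cameraPosition[3], config@cameraPitch * 180 / pi)

  withPrivateSeed(config@seed, {
    horizon <- duration * 60
    occupants <- .simulateOccupants(config, horizon)
    nFrames <- floor(horizon / frameInterval)
    times <- (seq_len(nFrames) - 1) * frameInterval
    base <- .renderBackground(config)
    npx <- length(base)
    frames <- vector("list", nFrames)
    gtFrames <- vector("list", nFrames)
    dupAfter <- logical(nFrames)

    for (k in seq_len(nFrames)) {
      t <- times[k]
      present <- occupants[occupants$tSit <= t & occupants$tLeave > t, ,
                           drop = FALSE]
      np <- nrow(present)
      depthM <- base * .depthNoise(npx, config@depthNoiseFrac)
      dets <- list()
      pass <- data.frame(id = character(), seat = character(),
                         busX = numeric(), busY = numeric(), busZ = numeric(),
                         camX = numeric(), camY = numeric(), camZ = numeric(),
                         u = numeric(), v = numeric(),
                         inView = logical(), detected = logical(),
                         stringsAsFactors = FALSE)
      noseBus <- NULL
      if (np > 0) {
        jitter <- matrix(rnorm(np * 3, 0, config@noseJitterSd), ncol = 3L)
        noseBus <- anchors3[present$seat, , drop = FALSE] + jitter
        noseCam <- .busToCamera(noseBus, config)
        prj <- projectPoint(noseCam, intr)
        inView <- prj[, 1] >= 0 & prj[, 1] < w & prj[, 2] >= 0 & prj[, 2] < h
        dropped <- runif(np) < config@detectionDropout
        for (i in seq_len(np)) {
          ## render the head: a small disc carrying the (noisy) nose Z-depth
          if (inView[i]) {
            ## nose-tip disc: ~2 cm physical radius (at least 2 px so the
            ## rounded centre pixel is always covered)
            rpx <- max(2L, as.integer(round(intr@fx * 0.02 / noseCam[i, 3])))
            uc <- roundHalfUp(prj[i, 1]); vc <- roundHalfUp(prj[i, 2])
            us <- max(0, uc - rpx):min(w - 1, uc + rpx)
            vs <- max(0, vc - rpx):min(h - 1, vc + rpx)
            cells <- expand.grid(v = vs, u = us)
            sel <- (cells$u - prj[i, 1])^2 + (cells$v - prj[i, 2])^2 <=
              (rpx + 0.1)^2
            idx <- cells$v[sel] + 1L + (cells$u[sel]) * h
            z <- noseCam[i, 3] * .depthNoise(sum(sel), config@depthNoiseFrac)
            depthM[idx] <- pmin(depthM[idx], z)
          }
          if (inView[i] && !dropped[i]) {
            kpBus <- sweep(.POSE_OFFSETS, 2, noseBus[i, ], "+")
            kpCam <- .busToCamera(kpBus, config)
            ok <- kpCam[, 3] > 0
            kpPx <- matrix(NA_real_, 17L, 2L)
            kpPx[ok, ] <- projectPoint(kpCam[ok, , drop = FALSE], intr)[, 1:2]
            conf <- c(runif(1, 0.85, 0.99), runif(16, 0.4, 0.95))
            bad <- !ok | kpPx[, 1] < 0 | kpPx[, 1] >= w |
                   kpPx[, 2] < 0 | kpPx[, 2] >= h
            conf[bad] <- 0
            kpPx[bad, 1] <- pmin(pmax(kpPx[bad, 1], 0), w - 1)
            kpPx[bad, 2] <- pmin(pmax(kpPx[bad, 2], 0), h - 1)
            kpPx[is.na(kpPx)] <- 0
            kp <- cbind(kpPx, conf)
            dimnames(kp) <- list(.COCO_NAMES, c("u", "v", "confidence"))
            dets[[length(dets) + 1L]] <-
              new("DetectionRecord", keypoints = kp,
                  detectionId = present$id[i])
          }
          pass[i, ] <- list(present$id[i], present$seat[i],
                            noseBus[i, 1], noseBus[i, 2], noseBus[i, 3],
                            noseCam[i, 1], noseCam[i, 2], noseCam[i, 3],
                            prj[i, 1], prj[i, 2], inView[i],
                            inView[i] && !dropped[i])
        }
      }
      dmat <- if (np > 0) as.matrix(dist(noseBus)) else
        matrix(numeric(0), 0, 0)
      if (np > 0) dimnames(dmat) <- list(present$id, present$id)
      raw <- as.integer(pmin(depthM * (1 / S), 65535) + 0.5)
      dim(raw) <- c(h, w)
      ## emit in captured orientation: the device is mounted upside-down,
      ## so frames leave the generator rotated 180 degrees from the
      ## analysis orientation used by the ground truth
      rawCap <- raw[h:1, w:1, drop = FALSE]
      detsCap <- lapply(dets, function(det) {
        kp <- det@keypoints
        kp[, 1] <- (w - 1) - kp[, 1]
        kp[, 2] <- (h - 1) - kp[, 2]
        det@keypoints <- kp
        det
      })
      frames[[k]] <- new("FrameRecord",
                         frameId = sprintf("frame-%05d", k),
                         timestamp = .BASE_TIME + t,
                         depth = rawCap, depthScale = S,
                         detections = detsCap, rotated = FALSE)
      gtFrames[[k]] <- list(passengers = pass, distances = dmat)
      dupAfter[k] <- runif(1) < config@duplicateFrameRate
    }

    ## inject byte-identical duplicate frames (storage-error emulation)
    outFrames <- list(); outGT <- list(); dupIdx <- integer()
    for (k in seq_len(nFrames)) {
      outFrames[[length(outFrames) + 1L]] <- frames[[k]]
      outGT[[length(outGT) + 1L]] <- gtFrames[[k]]
      if (dupAfter[k]) {
        dup <- frames[[k]]
        dup@frameId <- paste0(dup@frameId, "-dup")
        outFrames[[length(outFrames) + 1L]] <- dup
        outGT[[length(outGT) + 1L]] <- gtFrames[[k]]
        dupIdx <- c(dupIdx, length(outFrames))
      }
    }
    list(frames = outFrames,
         truth = list(frames = outGT, occupants = occupants,
                      duplicates = dupIdx, frameTimes = times,
                      config = config))
  })
}

#' Reference-point correspondences between image and bus plan
#'
#' Builds the correspondences used to estimate the perspective transform
#' from the horizontal distance plane to the bus plan: fixed interior
#' features (seat-back positions) whose pixel, depth and plan coordinates
#' are all known. Depths are quantised to the camera's depth unit, as a
#' measurement off a stored frame would be.
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param n number of reference points (default 15), taken evenly across
#'   the non-excluded seating positions
#' @return a data.frame with columns \code{u}, \code{v}, \code{depth_m},
#'   \code{plan_x_mm}, \code{plan_y_mm}, \code{tag}
#' @export
referenceCorrespondences <- function(config, n = 15L) {
  plan <- config@seatPlan
  labs <- sort(setdiff(names(seatPolygons(plan)), excludedSeats(plan)))
  if (length(labs) > n) {
    idx <- unique(roundHalfUp(seq(1, length(labs), length.out = n)))
    labs <- labs[idx]
  }
  anch <- seatAnchors(plan, labs)
  P <- cbind(anch$x / 1000, anch$y / 1000, config@seatAnchorHeight)
  cam <- .busToCamera(P, config)
  if (any(cam[, 3] <= 0))
    .stopf("reference point behind the camera; check the camera pose")
  px <- projectPoint(cam, config@intrinsics)
  S <- config@intrinsics@depthScale
  data.frame(u = px[, 1], v = px[, 2],
             depth_m = roundHalfUp(px[, 3]) * S,
             plan_x_mm = anch$x, plan_y_mm = anch$y,
             tag = "seat-back", stringsAsFactors = FALSE)
}
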