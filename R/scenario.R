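#' Default seat-choice preference weights
#'
#' A categorical seat-choice weight per seat, favouring window seats
#' (columns 1 and 4) over aisle seats (columns 2 and 3), with the back-row
#' middle seat in between; excluded seats get weight zero and are never
#' chosen by the generator.
#'
#' @param plan a \linkS4class{SeatPlan}
#' @param window,aisleSeat,middle weights for window, aisle-adjacent and
#'   back-row-middle positions
#' @return a named numeric vector over the plan's seats
#' @export
seatPreferenceWeights <- function(plan, window = 3, aisleSeat = 1,
                                  middle = 1.5) {
  labs <- names(seatPolygons(plan))
  w <- vapply(labs, function(l) {
    if (l == "FM") middle
    else if (substr(l, 2, 2) %in% c("1", "4")) window
    else aisleSeat
  }, numeric(1))
  w[labs %in% excludedSeats(plan)] <- 0
  w
}

#' Configure a synthetic bus scenario
#'
#' Bundles the generative assumptions behind the synthetic day: the camera
#' model and ceiling mounting pose, the seat plan and nose anchor height,
#' the memoryless boarding/alighting process (Poisson arrivals, exponential
#' dwell, blocked when every choosable seat is taken), seat preference
#' weights, fractional depth noise, detection dropout, and the rate at which
#' frames are re-emitted byte-identically (storage-error duplicates).
#'
#' Defaults place the camera on the ceiling (2.2 m) above the aisle at the
#' front bulkhead, pitched 25 degrees down towards the back of the bus, so
#' that all 25 visible seating positions project inside the usable image
#' area. Depth noise defaults to 2 percent of range, the nominal accuracy
#' class of the stereo device at 2 m.
#'
#' @param capacity visible seating capacity (occupancy denominator)
#' @param intrinsics a \linkS4class{CameraIntrinsics}
#' @param cameraPosition numeric(3) camera position in the bus frame (metres:
#'   x across, y along, z up)
#' @param cameraPitch,cameraYaw,cameraRoll mounting orientation in radians;
#'   positive pitch tilts the view downwards
#' @param seatPlan a \linkS4class{SeatPlan}
#' @param seatAnchorHeight height of a seated nose above the floor, metres
#' @param preferenceWeights named non-negative seat-choice weights
#' @param arrivalRate boarding rate, passengers per simulated minute
#' @param dwellTime mean ride duration in minutes (exponential)
#' @param noseJitterSd isotropic Gaussian jitter (sd, metres) of each nose
#'   around its seat anchor, avoiding degenerate exact-grid placements
#' @param depthNoiseFrac fractional Gaussian depth noise (sd = frac x depth)
#' @param detectionDropout probability a present passenger yields no
#'   detection in a frame
#' @param duplicateFrameRate probability a frame is emitted twice
#'   byte-identically
#' @param seed integer RNG seed
#' @return a \linkS4class{ScenarioConfig}
#' @examples
#' cfg <- scenarioConfig(seed = 1)
#' cfg
#' @export
scenarioConfig <- function(capacity = 25L,
                           intrinsics = busIntrinsics(),
                           cameraPosition = c(1.2, 0, 2.2),
                           cameraPitch = 25 * pi / 180,
                           cameraYaw = 0, cameraRoll = 0,
                           seatPlan = busSeatPlan(),
                           seatAnchorHeight = 1.2,
                           preferenceWeights = seatPreferenceWeights(seatPlan),
                           arrivalRate = 0.3, dwellTime = 10,
                           noseJitterSd = 0.03,
                           depthNoiseFrac = 0.02,
                           detectionDropout = 0.05,
                           duplicateFrameRate = 0.01,
                           seed = 42L) {
  new("ScenarioConfig", capacity = as.integer(capacity),
      intrinsics = intrinsics, cameraPosition = as.numeric(cameraPosition),
      cameraPitch = cameraPitch, cameraYaw = cameraYaw,
      cameraRoll = cameraRoll, seatPlan = seatPlan,
      seatAnchorHeight = seatAnchorHeight,
      preferenceWeights = preferenceWeights,
      arrivalRate = arrivalRate, dwellTime = dwellTime,
      noseJitterSd = noseJitterSd, depthNoiseFrac = depthNoiseFrac,
      detectionDropout = detectionDropout,
      duplicateFrameRate = duplicateFrameRate,
      seed = as.integer(seed))
}

## Rotation matrix taking bus-frame vectors to camera-frame vectors.
## Bus frame: x across, y along (towards the back), z up. With zero
## pitch/yaw/roll the camera looks along +y with X right (+x) and Y down.
.cameraRotation <- function(config) {
  base <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  p <- config@cameraPitch; yw <- config@cameraYaw; rl <- config@cameraRoll
  rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  rz <- rbind(c(cos(rl), -sin(rl), 0), c(sin(rl), cos(rl), 0), c(0, 0, 1))
  ryaw <- rbind(c(cos(yw), -sin(yw), 0), c(sin(yw), cos(yw), 0), c(0, 0, 1))
  rz %*% rx %*% base %*% t(ryaw)
}

## Bus-frame (metres) -> camera-frame (metres).
.busToCamera <- function(P, config) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3L, byrow = TRUE)
  R <- .cameraRotation(config)
  t(R %*% (t(P) - config@cameraPosition))
}

## Camera-frame -> bus-frame.
.cameraToBus <- function(P, config) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3L, byrow = TRUE)
  R <- .cameraRotation(config)
  t(t(R) %*% t(P) + config@cameraPosition)
}
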