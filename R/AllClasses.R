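## Central S4 containers. All pixel coordinates in this package are 0-based
## with origin at the top-left corner, u = column, v = row (image convention);
## plan coordinates are millimetres with origin at the front-offside corner of
## the bus, x across the vehicle (offside -> nearside), y along it
## (front -> back).

#' Pinhole camera intrinsics with optional Brown-Conrady distortion
#'
#' Describes the depth camera: image size, focal lengths and principal point
#' in pixels, distortion model, nominal horizontal/vertical fields of view in
#' degrees, and the depth scale \code{S} converting raw 16-bit depth units to
#' metres. Raw depth values are Z-depth (distance along the optical axis), not
#' Euclidean range.
#'
#' @slot width,height image size in pixels
#' @slot fx,fy focal lengths in pixels
#' @slot cx,cy principal point in pixels
#' @slot distortionModel \code{"none"} or \code{"brown_conrady"}
#' @slot distortionCoeffs numeric(5): k1, k2, p1, p2, k3
#' @slot hfov,vfov nominal fields of view in degrees
#' @slot depthScale metres per raw depth unit
#' @exportClass CameraIntrinsics
setClass("CameraIntrinsics",
  representation(width = "integer", height = "integer",
                 fx = "numeric", fy = "numeric",
                 cx = "numeric", cy = "numeric",
                 distortionModel = "character",
                 distortionCoeffs = "numeric",
                 hfov = "numeric", vfov = "numeric",
                 depthScale = "numeric"))

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "image size must be positive")
  if (object@fx <= 0 || object@fy <= 0) msg <- c(msg, "fx and fy must be > 0")
  if (!(object@cx > 0 && object@cx < object@width))
    msg <- c(msg, "cx must lie strictly inside [0, width]")
  if (!(object@cy > 0 && object@cy < object@height))
    msg <- c(msg, "cy must lie strictly inside [0, height]")
  if (object@depthScale <= 0) msg <- c(msg, "depthScale must be > 0")
  if (!object@distortionModel %in% c("none", "brown_conrady"))
    msg <- c(msg, "unsupported distortion model")
  if (length(object@distortionCoeffs) != 5L)
    msg <- c(msg, "distortionCoeffs must have length 5")
  if (object@distortionModel == "none") {
    implied <- 2 * atan(object@width / (2 * object@fx)) * 180 / pi
    if (abs(implied - object@hfov) > 1)
      msg <- c(msg, sprintf("hfov (%.2f deg) inconsistent with fx/width (implies %.2f deg)",
                            object@hfov, implied))
  }
  if (length(msg)) msg else TRUE
})

#' One passenger detection: a 17-keypoint COCO skeleton
#'
#' Keypoints are stored as a 17 x 3 matrix with columns \code{u}, \code{v}
#' (0-based pixel coordinates) and \code{confidence} in [0, 1], rows in COCO
#' order; row 1 is the nose, the anchor for all downstream measurement.
#'
#' @slot keypoints 17 x 3 numeric matrix (u, v, confidence)
#' @slot detectionId character identifier, unique within a frame
#' @exportClass DetectionRecord
setClass("DetectionRecord",
  representation(keypoints = "matrix", detectionId = "character"))

setValidity("DetectionRecord", function(object) {
  kp <- object@keypoints
  msg <- character()
  if (!is.numeric(kp) || nrow(kp) != 17L || ncol(kp) != 3L)
    msg <- c(msg, "keypoints must be a 17 x 3 numeric matrix")
  else if (any(kp[, 3] < 0 | kp[, 3] > 1, na.rm = TRUE))
    msg <- c(msg, "confidences must lie in [0, 1]")
  if (length(object@detectionId) != 1L)
    msg <- c(msg, "detectionId must be a single string")
  if (length(msg)) msg else TRUE
})

#' A timestamped depth frame with its passenger detections
#'
#' @slot frameId character frame identifier
#' @slot timestamp POSIXct capture time
#' @slot depth height x width integer matrix of raw 16-bit depth units;
#'   0 encodes invalid depth
#' @slot depthScale metres per raw unit (S)
#' @slot detections list of \linkS4class{DetectionRecord}
#' @slot rotated logical; TRUE once the 180-degree orientation fix has been
#'   applied
#' @exportClass FrameRecord
setClass("FrameRecord",
  representation(frameId = "character", timestamp = "POSIXct",
                 depth = "matrix", depthScale = "numeric",
                 detections = "list", rotated = "logical"))

setValidity("FrameRecord", function(object) {
  msg <- character()
  if (!is.integer(object@depth))
    msg <- c(msg, "depth must be an integer matrix of raw 16-bit units")
  else if (any(object@depth < 0L | object@depth > 65535L))
    msg <- c(msg, "raw depth values must lie in [0, 65535]")
  if (object@depthScale <= 0) msg <- c(msg, "depthScale must be > 0")
  if (!all(vapply(object@detections, is, logical(1), "DetectionRecord")))
    msg <- c(msg, "detections must all be DetectionRecord objects")
  if (length(msg)) msg else TRUE
})

#' Named exclusion polygons in image coordinates
#'
#' Regions of the image (handrails, reflective surfaces, depth shadows) whose
#' detections are discarded during preprocessing.
#'
#' @slot polygons named list of n x 2 matrices of (u, v) pixel vertices
#' @slot imageSize integer(2): width, height in pixels
#' @exportClass MaskSet
setClass("MaskSet",
  representation(polygons = "list", imageSize = "integer"))

setValidity("MaskSet", function(object) {
  msg <- character()
  w <- object@imageSize[1]; h <- object@imageSize[2]
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msg <- c(msg, "imageSize must be two positive integers")
  nms <- names(object@polygons)
  if (length(object@polygons) && (is.null(nms) || any(nms == "")))
    msg <- c(msg, "all mask polygons must be named")
  for (nm in nms) {
    p <- object@polygons[[nm]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
      msg <- c(msg, sprintf("polygon '%s' is not an n x 2 matrix with n >= 3", nm))
      next
    }
    if (any(p[, 1] < 0 | p[, 1] > w | p[, 2] < 0 | p[, 2] > h))
      msg <- c(msg, sprintf("polygon '%s' has vertices outside the image", nm))
    if (!isSimplePolygon(p))
      msg <- c(msg, sprintf("polygon '%s' is self-intersecting", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Labelled bus floor plan
#'
#' Seat polygons are named by row letter (A-F, front to back) and column
#' number (1-4, offside to nearside), plus \code{FM} for the middle seat of
#' the back row. The aisle is an explicit polygon. Seats on the
#' \code{excluded} list exist in the plan but are never returned by
#' allocation (positions where detections are unreliable).
#'
#' @slot seats named list of n x 2 polygon matrices in plan millimetres
#' @slot aisle n x 2 polygon matrix for the aisle
#' @slot excluded character vector of seat labels excluded from analysis
#' @exportClass SeatPlan
setClass("SeatPlan",
  representation(seats = "list", aisle = "matrix", excluded = "character"))

setValidity("SeatPlan", function(object) {
  msg <- character()
  nms <- names(object@seats)
  if (is.null(nms) || any(nms == "")) msg <- c(msg, "all seats must be named")
  polys <- c(object@seats, list(aisle = object@aisle))
  for (nm in names(polys)) {
    p <- polys[[nm]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      msg <- c(msg, sprintf("polygon '%s' is not an n x 2 matrix with n >= 3", nm))
    else if (!isSimplePolygon(p))
      msg <- c(msg, sprintf("polygon '%s' is self-intersecting", nm))
  }
  if (!length(msg)) {
    labs <- names(polys)
    for (i in seq_along(polys)) for (j in seq_len(i - 1L))
      if (.polygonsOverlap(polys[[i]], polys[[j]]))
        msg <- c(msg, sprintf("polygons '%s' and '%s' have overlapping interiors",
                              labs[j], labs[i]))
  }
  if (!all(object@excluded %in% nms))
    msg <- c(msg, "excluded labels must name seats in the plan")
  if (length(msg)) msg else TRUE
})

#' Scenario configuration for the synthetic bus-scene generator
#'
#' Houses the generative assumptions: camera model and mounting pose, seat
#' layout and anchor height, the memoryless boarding/alighting process, seat
#' preference weights, depth-noise level, detection dropout, and duplicate
#' frame injection.
#'
#' @slot capacity visible seating capacity used as the occupancy denominator
#' @slot intrinsics a \linkS4class{CameraIntrinsics}
#' @slot cameraPosition numeric(3) camera position in bus frame, metres
#'   (x across, y along, z up)
#' @slot cameraPitch,cameraYaw,cameraRoll mounting orientation, radians;
#'   pitch > 0 tilts the view downwards
#' @slot seatPlan a \linkS4class{SeatPlan}
#' @slot seatAnchorHeight metres above floor of a seated nose
#' @slot preferenceWeights named non-negative seat-choice weights; zero-weight
#'   seats are never chosen
#' @slot arrivalRate boarding rate, passengers per simulated minute
#' @slot dwellTime mean ride duration, minutes (exponential)
#' @slot noseJitterSd isotropic Gaussian jitter of nose positions around the
#'   seat anchor, metres
#' @slot depthNoiseFrac fractional Gaussian depth noise (sd = frac x depth)
#' @slot detectionDropout probability a present passenger yields no detection
#' @slot duplicateFrameRate probability a frame is re-emitted byte-identically
#' @slot seed integer RNG seed
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(capacity = "integer", intrinsics = "CameraIntrinsics",
                 cameraPosition = "numeric", cameraPitch = "numeric",
                 cameraYaw = "numeric", cameraRoll = "numeric",
                 seatPlan = "SeatPlan", seatAnchorHeight = "numeric",
                 preferenceWeights = "numeric", arrivalRate = "numeric",
                 dwellTime = "numeric", noseJitterSd = "numeric",
                 depthNoiseFrac = "numeric",
                 detectionDropout = "numeric", duplicateFrameRate = "numeric",
                 seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@capacity < 1L) msg <- c(msg, "capacity must be >= 1")
  w <- object@preferenceWeights
  if (length(w) == 0L || any(w < 0) || all(w == 0))
    msg <- c(msg, "preference weights must be non-negative with at least one > 0")
  if (!all(names(w) %in% names(object@seatPlan@seats)))
    msg <- c(msg, "preference weights must be named after plan seats")
  if (length(object@cameraPosition) != 3L)
    msg <- c(msg, "cameraPosition must be numeric(3)")
  if (object@seatAnchorHeight <= 0) msg <- c(msg, "seatAnchorHeight must be > 0")
  if (object@arrivalRate < 0 || object@dwellTime <= 0)
    msg <- c(msg, "arrivalRate must be >= 0 and dwellTime > 0")
  if (object@depthNoiseFrac < 0) msg <- c(msg, "depthNoiseFrac must be >= 0")
  if (object@noseJitterSd < 0) msg <- c(msg, "noseJitterSd must be >= 0")
  for (p in c("detectionDropout", "duplicateFrameRate"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  if (length(msg)) msg else TRUE
})

#' Robust planar homography
#'
#' The 3 x 3 perspective transform from the horizontal distance plane (metres)
#' to the bus plan (millimetres), estimated by least median of squares,
#' normalised so the bottom-right element equals 1.
#'
#' @slot H 3 x 3 matrix
#' @slot inliers logical mask over the correspondences used in estimation
#' @slot medianResidual robust score: median squared plan-space residual
#'   (mm^2) at the selected model, before the inlier refit
#' @exportClass Homography
setClass("Homography",
  representation(H = "matrix", inliers = "logical", medianResidual = "numeric"))

setValidity("Homography", function(object) {
  msg <- character()
  if (!all(dim(object@H) == c(3L, 3L))) msg <- c(msg, "H must be 3 x 3")
  else {
    if (abs(det(object@H)) < .Machine$double.eps)
      msg <- c(msg, "H must be invertible")
    if (abs(object@H[3, 3] - 1) > 1e-9)
      msg <- c(msg, "H must be normalised so H[3,3] = 1")
  }
  if (length(msg)) msg else TRUE
})

#' Exposure statistics per occupancy level
#'
#' Per occupancy level (integer percent of visible capacity): the number of
#' analysed images, and per risk band the total instance count, mean
#' instances per image, and the individual likelihood (mean over images of
#' the fraction of individuals with at least one partner at a band distance).
#'
#' @slot capacity occupancy denominator (seats visible to the camera)
#' @slot weighting \code{"per_image"} (mean of per-image proportions) or
#'   \code{"pooled"} (pooled individual counts)
#' @slot bands data.frame: level, band, total, meanPerImage, likelihood
#' @slot imageCounts data.frame: level, images
#' @slot analysedFrames number of frames with >= 2 detections
#' @slot totalFrames number of frames summarised over
#' @exportClass RiskSummary
setClass("RiskSummary",
  representation(capacity = "integer", weighting = "character",
                 bands = "data.frame", imageCounts = "data.frame",
                 analysedFrames = "integer", totalFrames = "integer"))

setValidity("RiskSummary", function(object) {
  msg <- character()
  b <- object@bands
  if (!all(c("level", "band", "total", "meanPerImage", "likelihood") %in% names(b)))
    msg <- c(msg, "bands table is missing columns")
  else if (any(b$likelihood < -1e-12 | b$likelihood > 1 + 1e-12))
    msg <- c(msg, "likelihoods must lie in [0, 1]")
  if (sum(object@imageCounts$images) != object@analysedFrames)
    msg <- c(msg, "image counts must sum to the number of analysed frames")
  if (length(msg)) msg else TRUE
})

#' Run-level accounting summary
#'
#' Cross-footed counts for a full processing run: frames and detections in,
#' survivors of each preprocessing filter, pair measurements taken and
#' skipped, seat allocations, and the allocation rate.
#'
#' @slot frames frames entering the pipeline
#' @slot duplicatesRemoved byte-identical frames removed
#' @slot detectionsIn detections before filtering
#' @slot afterConfidence,afterBorder,afterMask survivors of each filter stage
#' @slot pairsMeasured,pairsSkipped valid and invalid-depth pair measurements
#' @slot allocations detections allocated to a seat or the aisle
#' @slot allocationRate allocations / surviving detections (NA if none)
#' @exportClass RunReport
setClass("RunReport",
  representation(frames = "numeric", duplicatesRemoved = "numeric",
                 detectionsIn = "numeric", afterConfidence = "numeric",
                 afterBorder = "numeric", afterMask = "numeric",
                 pairsMeasured = "numeric", pairsSkipped = "numeric",
                 allocations = "numeric", allocationRate = "numeric"))

setValidity("RunReport", function(object) {
  msg <- character()
  counts <- c(object@frames, object@duplicatesRemoved, object@detectionsIn,
              object@afterConfidence, object@afterBorder, object@afterMask,
              object@pairsMeasured, object@pairsSkipped, object@allocations)
  if (any(counts < 0)) msg <- c(msg, "counts must be non-negative")
  chain <- c(object@detectionsIn, object@afterConfidence, object@afterBorder,
             object@afterMask)
  if (any(diff(chain) > 0))
    msg <- c(msg, "filter chain counts must be non-increasing")
  if (object@allocations > object@afterMask)
    msg <- c(msg, "allocations cannot exceed surviving detections")
  if (!is.na(object@allocationRate) &&
      (object@allocationRate < 0 || object@allocationRate > 1))
    msg <- c(msg, "allocation rate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
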