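## Generics, accessors and show methods.

#' @rdname FrameRecord-class
#' @param object,x an object
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))
#' @rdname FrameRecord-class
#' @export
setGeneric("depthScale", function(x) standardGeneric("depthScale"))
#' @rdname FrameRecord-class
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @rdname FrameRecord-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))
#' @rdname DetectionRecord-class
#' @param x an object
#' @export
setGeneric("keypoints", function(x) standardGeneric("keypoints"))
#' @rdname DetectionRecord-class
#' @export
setGeneric("nosePoint", function(x) standardGeneric("nosePoint"))
#' @rdname SeatPlan-class
#' @export
setGeneric("seatPolygons", function(x) standardGeneric("seatPolygons"))
#' @rdname SeatPlan-class
#' @export
setGeneric("aislePolygon", function(x) standardGeneric("aislePolygon"))
#' @rdname SeatPlan-class
#' @export
setGeneric("excludedSeats", function(x) standardGeneric("excludedSeats"))
#' @rdname Homography-class
#' @export
setGeneric("homographyMatrix", function(x) standardGeneric("homographyMatrix"))
#' @rdname Homography-class
#' @export
setGeneric("inlierMask", function(x) standardGeneric("inlierMask"))
#' @rdname RiskSummary-class
#' @export
setGeneric("riskTable", function(x) standardGeneric("riskTable"))
#' @rdname RiskSummary-class
#' @export
setGeneric("imageDistribution", function(x) standardGeneric("imageDistribution"))

#' @rdname FrameRecord-class
setMethod("depthMatrix", "FrameRecord", function(x) x@depth)
#' @rdname FrameRecord-class
setMethod("depthScale", "FrameRecord", function(x) x@depthScale)
#' @rdname FrameRecord-class
setMethod("detections", "FrameRecord", function(x) x@detections)
#' @rdname FrameRecord-class
setMethod("frameId", "FrameRecord", function(x) x@frameId)
#' @rdname DetectionRecord-class
setMethod("keypoints", "DetectionRecord", function(x) x@keypoints)
#' @rdname DetectionRecord-class
setMethod("nosePoint", "DetectionRecord", function(x) x@keypoints[1L, ])
#' @rdname SeatPlan-class
setMethod("seatPolygons", "SeatPlan", function(x) x@seats)
#' @rdname SeatPlan-class
setMethod("aislePolygon", "SeatPlan", function(x) x@aisle)
#' @rdname SeatPlan-class
setMethod("excludedSeats", "SeatPlan", function(x) x@excluded)
#' @rdname Homography-class
setMethod("homographyMatrix", "Homography", function(x) x@H)
#' @rdname Homography-class
setMethod("inlierMask", "Homography", function(x) x@inliers)
#' @rdname RiskSummary-class
setMethod("riskTable", "RiskSummary", function(x) x@bands)
#' @rdname RiskSummary-class
setMethod("imageDistribution", "RiskSummary", function(x) x@imageCounts)

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %dx%d px, fx=%.2f fy=%.2f, c=(%.1f, %.1f)\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy))
  cat(sprintf("  FOV %.1f x %.1f deg, distortion: %s, depth scale S=%g m/unit\n",
              object@hfov, object@vfov, object@distortionModel,
              object@depthScale))
})

setMethod("show", "FrameRecord", function(object) {
  cat(sprintf("FrameRecord '%s' @ %s: %dx%d depth (S=%g), %d detection(s)%s\n",
              object@frameId, format(object@timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                     tz = "UTC"),
              ncol(object@depth), nrow(object@depth), object@depthScale,
              length(object@detections),
              if (object@rotated) ", rotated" else ""))
})

setMethod("show", "SeatPlan", function(object) {
  cat(sprintf("SeatPlan: %d seats (+aisle), %d excluded (%s)\n",
              length(object@seats), length(object@excluded),
              paste(object@excluded, collapse = ", ")))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(paste0("ScenarioConfig: capacity %d, arrivals %.2f/min, ",
                     "dwell %.1f min, depth noise %.1f%%, dropout %.2f, ",
                     "seed %d\n"),
              object@capacity, object@arrivalRate, object@dwellTime,
              100 * object@depthNoiseFrac, object@detectionDropout,
              object@seed))
  cat(sprintf("  camera at (%.2f, %.2f, %.2f) m, pitch %.1f deg\n",
              object@cameraPosition[1], object@cameraPosition[2],
              object@cameraPosition[3], object@cameraPitch * 180 / pi))
})

setMethod("show", "Homography", function(object) {
  cat(sprintf("Homography: %d/%d inliers, median squared residual %.3g\n",
              sum(object@inliers), length(object@inliers),
              object@medianResidual))
  print(round(object@H, 6))
})

setMethod("show", "RiskSummary", function(object) {
  cat(sprintf(paste0("RiskSummary (%s): %d analysed frames (>=2 detections) ",
                     "of %d, capacity %d\n"),
              object@weighting, object@analysedFrames, object@totalFrames,
              object@capacity))
  print(head(object@bands, 9))
  if (nrow(object@bands) > 9) cat("  ...\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  cat(sprintf("  frames: %d (duplicates removed: %d)\n",
              object@frames, object@duplicatesRemoved))
  cat(sprintf("  detections: %d -> conf %d -> border %d -> mask %d\n",
              object@detectionsIn, object@afterConfidence,
              object@afterBorder, object@afterMask))
  cat(sprintf("  pairs measured: %d, skipped (invalid depth): %d\n",
              object@pairsMeasured, object@pairsSkipped))
  rate <- if (is.na(object@allocationRate)) "undefined"
          else sprintf("%.4f (%d%%)", object@allocationRate,
                       as.integer(roundHalfUp(100 * object@allocationRate)))
  cat(sprintf("  seat allocations: %d, allocation rate: %s\n",
              object@allocations, rate))
})
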