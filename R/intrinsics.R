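#' Construct camera intrinsics
#'
#' @param width,height image size in pixels
#' @param fx,fy focal lengths in pixels; by default derived from the fields of
#'   view as \code{fx = width / (2 tan(hfov/2))} (and analogously for fy)
#' @param cx,cy principal point; defaults to the image centre
#' @param hfov,vfov nominal horizontal/vertical fields of view in degrees
#' @param distortionModel \code{"none"} or \code{"brown_conrady"}
#' @param distortionCoeffs numeric(5): k1, k2, p1, p2, k3
#' @param depthScale metres per raw depth unit (S)
#' @return a \linkS4class{CameraIntrinsics}
#' @examples
#' intr <- busIntrinsics()
#' projectPoint(c(0, 0, 2), intr)
#' @export
cameraIntrinsics <- function(width = 640L, height = 480L,
                             hfov = 74, vfov = 62,
                             fx = width / (2 * tan(hfov * pi / 360)),
                             fy = height / (2 * tan(vfov * pi / 360)),
                             cx = width / 2, cy = height / 2,
                             distortionModel = c("none", "brown_conrady"),
                             distortionCoeffs = numeric(5),
                             depthScale = 0.001) {
  distortionModel <- match.arg(distortionModel)
  new("CameraIntrinsics", width = as.integer(width), height = as.integer(height),
      fx = fx, fy = fy, cx = cx, cy = cy,
      distortionModel = distortionModel,
      distortionCoeffs = as.numeric(distortionCoeffs),
      hfov = hfov, vfov = vfov, depthScale = depthScale)
}

#' Default intrinsics of the ceiling-mounted bus depth camera
#'
#' A VGA (640 x 480) stereo depth camera with 74 x 62 degree fields of view
#' and a 1 mm depth unit, matching the class of low-cost RGB-D devices used
#' for in-vehicle capture.
#'
#' @inheritParams cameraIntrinsics
#' @return a \linkS4class{CameraIntrinsics}
#' @export
busIntrinsics <- function(depthScale = 0.001) {
  cameraIntrinsics(depthScale = depthScale)
}

## Brown-Conrady forward distortion on normalised image coordinates.
.distort <- function(x, y, k) {
  r2 <- x * x + y * y
  rad <- 1 + k[1] * r2 + k[2] * r2^2 + k[5] * r2^3
  list(x = x * rad + 2 * k[3] * x * y + k[4] * (r2 + 2 * x * x),
       y = y * rad + k[3] * (r2 + 2 * y * y) + 2 * k[4] * x * y)
}

## Iterative inversion of .distort (fixed point on the radial factor).
.undistort <- function(xd, yd, k, iters = 25L) {
  x <- xd; y <- yd
  for (i in seq_len(iters)) {
    r2 <- x * x + y * y
    rad <- 1 + k[1] * r2 + k[2] * r2^2 + k[5] * r2^3
    dx <- 2 * k[3] * x * y + k[4] * (r2 + 2 * x * x)
    dy <- k[3] * (r2 + 2 * y * y) + 2 * k[4] * x * y
    x <- (xd - dx) / rad
    y <- (yd - dy) / rad
  }
  list(x = x, y = y)
}

#' Project camera-frame 3D points to pixels (forward pinhole model)
#'
#' The inverse of \code{\link{deprojectPixel}}. The camera frame has X right,
#' Y down, Z forward along the optical axis; only points with Z > 0 are in
#' front of the camera.
#'
#' @param P numeric(3) or n x 3 matrix of camera-frame points (metres)
#' @param intr a \linkS4class{CameraIntrinsics}
#' @return an n x 3 matrix with columns \code{u}, \code{v} (0-based pixels)
#'   and \code{depth} (raw depth units, Z / S, unquantised)
#' @export
projectPoint <- function(P, intr) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3L, byrow = TRUE)
  stopifnot(ncol(P) == 3L)
  if (any(P[, 3] <= 0))
    .stopf("cannot project point(s) with Z <= 0 (behind the camera)")
  x <- P[, 1] / P[, 3]; y <- P[, 2] / P[, 3]
  if (intr@distortionModel == "brown_conrady") {
    d <- .distort(x, y, intr@distortionCoeffs)
    x <- d$x; y <- d$y
  }
  cbind(u = intr@cx + intr@fx * x,
        v = intr@cy + intr@fy * y,
        depth = P[, 3] / intr@depthScale)
}

#' Deproject pixels with depth to camera-frame 3D points
#'
#' Recovers the 3D point along the ray through pixel (u, v) at the given
#' Z-depth, using the intrinsic camera model (focal lengths, principal point,
#' distortion). For the undistorted model,
#' \code{X = (u - cx)/fx * Z}, \code{Y = (v - cy)/fy * Z}, \code{Z = depth};
#' Brown-Conrady distortion is inverted iteratively before the pinhole step.
#'
#' @param u,v 0-based pixel coordinates (numeric vectors); values outside
#'   the image are accepted (the pixel grid merely parameterises rays)
#' @param depth Z-depth in metres (already scaled by S); must be > 0
#' @param intr a \linkS4class{CameraIntrinsics}
#' @return an n x 3 matrix with columns \code{X}, \code{Y}, \code{Z} (metres)
#' @examples
#' intr <- busIntrinsics()
#' deprojectPixel(320, 240, 2, intr)   # on the optical axis: (0, 0, 2)
#' @export
deprojectPixel <- function(u, v, depth, intr) {
  if (any(depth <= 0)) .stopf("depth must be > 0 for deprojection")
  x <- (u - intr@cx) / intr@fx
  y <- (v - intr@cy) / intr@fy
  if (intr@distortionModel == "brown_conrady") {
    und <- .undistort(x, y, intr@distortionCoeffs)
    x <- und$x; y <- und$y
  }
  cbind(X = x * depth, Y = y * depth, Z = depth)
}
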