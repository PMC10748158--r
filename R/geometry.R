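## Metric measurement chain: depth lookup -> scale -> deprojection ->
## Euclidean nose-to-nose distance.

#' Look up metric depth at a pixel
#'
#' Reads the raw 16-bit value at (u, v) (0-based pixel coordinates; floats
#' are rounded half-up to the nearest pixel centre) and scales it by the
#' frame's depth unit S. A raw value of 0 encodes invalid depth and is
#' signalled as \code{NA} (not returned as 0 m). An optional 3 x 3 median
#' fallback can patch an invalid centre pixel; it is off by default, since
#' the measurement protocol is a direct single-pixel lookup.
#'
#' @param frame a \linkS4class{FrameRecord}
#' @param u,v pixel coordinates (0-based; u = column from the left,
#'   v = row from the top)
#' @param medianFallback use the median of the valid 3 x 3 neighbourhood
#'   when the centre pixel is invalid
#' @return depth in metres, or \code{NA_real_} for invalid depth
#' @export
depthAt <- function(frame, u, v, medianFallback = FALSE) {
  d <- frame@depth
  h <- nrow(d); w <- ncol(d)
  ui <- roundHalfUp(u); vi <- roundHalfUp(v)
  if (ui < 0 || ui >= w || vi < 0 || vi >= h)
    .stopf("pixel (%g, %g) out of bounds for a %dx%d image", u, v, w, h)
  raw <- d[vi + 1L, ui + 1L]
  if (raw == 0L && medianFallback) {
    us <- max(0L, ui - 1L):min(w - 1L, ui + 1L)
    vs <- max(0L, vi - 1L):min(h - 1L, vi + 1L)
    nb <- d[vs + 1L, us + 1L]
    nb <- nb[nb > 0L]
    if (length(nb)) raw <- as.integer(median(nb))
  }
  if (raw == 0L) return(NA_real_)
  raw * frame@depthScale
}

#' Nose-to-nose distance between two passengers
#'
#' Deprojects both (u, v, depth) triples to 3D camera-frame points and
#' returns their Euclidean (Pythagorean) distance in metres. If either
#' depth is missing (\code{NA}) the measurement is skipped and
#' \code{NA_real_} returned with a \code{reason} attribute, rather than
#' raising an error.
#'
#' @param p0,p1 numeric(3): (u, v, depth in metres); depth may be \code{NA}
#' @param intr a \linkS4class{CameraIntrinsics}
#' @return distance in metres, or \code{NA_real_} with a \code{reason}
#'   attribute when a depth is invalid
#' @examples
#' intr <- busIntrinsics()
#' noseToNose(c(320, 240, 2), c(320, 240, 2), intr)   # 0
#' @export
noseToNose <- function(p0, p1, intr) {
  if (is.na(p0[3]) || is.na(p1[3])) {
    out <- NA_real_
    attr(out, "reason") <- "invalid depth"
    return(out)
  }
  P <- deprojectPixel(c(p0[1], p1[1]), c(p0[2], p1[2]), c(p0[3], p1[3]), intr)
  sqrt(sum((P[1, ] - P[2, ])^2))
}

#' Polar bearing of a pixel column
#'
#' The bearing used in building the horizontal distance plane:
#' \code{theta = u * HFOV / w} degrees, 0 at the left image edge and HFOV at
#' the right edge. The absolute angular reference is a free gauge absorbed
#' by the plan homography.
#'
#' @param u pixel column (0-based; \code{u = w} maps to exactly HFOV)
#' @param D horizontal range in metres (returned unchanged)
#' @param intr a \linkS4class{CameraIntrinsics}
#' @return a matrix with columns \code{D} (metres) and \code{theta}
#'   (degrees)
#' @export
polarOf <- function(u, D, intr) {
  if (any(u < 0 | u > intr@width)) .stopf("u out of [0, width]")
  if (any(D <= 0)) .stopf("D must be > 0")
  cbind(D = D, theta = u * intr@hfov / intr@width)
}
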