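## Mapping passengers onto the bus plan: horizontal distance plane, robust
## (least-median-of-squares) perspective transform, point-in-polygon seat
## allocation, and occupancy time series.

#' Project an image measurement onto the horizontal distance plane
#'
#' Deprojects (u, v, depth) to 3D, removes the vertical component of the
#' point (horizontal range \code{r = sqrt(X^2 + Z^2)}), takes the bearing
#' \code{theta = u * HFOV / w}, and converts the polar position to Cartesian
#' coordinates \code{(r sin(theta - HFOV/2), r cos(theta - HFOV/2))} in
#' metres. The centring of the bearing is a free gauge absorbed by the plan
#' homography.
#'
#' @param u,v pixel coordinates (0-based, vectorised)
#' @param depth Z-depth in metres; \code{NA} entries are propagated
#' @param intr a \linkS4class{CameraIntrinsics}
#' @return an n x 2 matrix of distance-plane (x, y) in metres
#' @export
toDistancePlane <- function(u, v, depth, intr) {
  out <- matrix(NA_real_, length(u), 2L, dimnames = list(NULL, c("x", "y")))
  ok <- !is.na(depth)
  if (any(ok)) {
    P <- deprojectPixel(u[ok], v[ok], depth[ok], intr)
    r <- sqrt(P[, "X"]^2 + P[, "Z"]^2)
    theta <- polarOf(u[ok], r, intr)[, "theta"]
    a <- (theta - intr@hfov / 2) * pi / 180
    out[ok, ] <- cbind(r * sin(a), r * cos(a))
  }
  out
}

## Hartley-normalised direct linear transform for a homography from >= 4
## correspondences (least squares via SVD).
.normalise2d <- function(P) {
  mu <- colMeans(P)
  d <- sqrt(rowSums(sweep(P, 2, mu)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
  list(T = T, P = cbind(s * (P[, 1] - mu[1]), s * (P[, 2] - mu[2])))
}

.solveDLT <- function(src, dst) {
  ns <- .normalise2d(src); nd <- .normalise2d(dst)
  x <- ns$P[, 1]; y <- ns$P[, 2]; xp <- nd$P[, 1]; yp <- nd$P[, 2]
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, x * xp, y * xp, xp)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, x * yp, y * yp, yp)
  sv <- svd(A, nv = 9)
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

## Any 3 of the 4 sample points collinear (degenerate minimal sample)?
.degenerateQuad <- function(P) {
  idx <- combn(4L, 3L)
  for (k in 1:4) {
    a <- P[idx[1, k], ]; b <- P[idx[2, k], ]; c <- P[idx[3, k], ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    scale <- max(abs(c(a, b, c)), 1)
    if (abs(cr) < 1e-9 * scale^2) return(TRUE)
  }
  FALSE
}

.squaredResiduals <- function(H, src, dst) {
  p <- cbind(src, 1) %*% t(H)
  rowSums((p[, 1:2] / p[, 3] - dst)^2)
}

#' Estimate a robust plan homography by least median of squares
#'
#' Fits the 3 x 3 perspective transform from distance-plane coordinates
#' (metres) to bus-plan coordinates (millimetres). Minimal 4-point samples
#' are drawn (exhaustively when there are no more than \code{nSamples}
#' combinations, otherwise at random) and scored by the median squared
#' plan-space residual over all correspondences; the best model's robust
#' scale \code{1.4826 (1 + 5/(n-4)) sqrt(med)} defines inliers at 2.5
#' scales, on which an ordinary least-squares fit is returned. LMedS
#' tolerates up to half the correspondences being grossly wrong without any
#' tuning threshold.
#'
#' @param src n x 2 matrix of distance-plane points (metres)
#' @param dst n x 2 matrix of plan points (millimetres)
#' @param seed RNG seed for the random minimal samples (deterministic
#'   result for a fixed seed)
#' @param nSamples number of minimal samples (default 1000)
#' @return a \linkS4class{Homography}
#' @export
estimateHomography <- function(src, dst, seed = 1L, nSamples = 1000L) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n)
    .stopf("need >= 4 source/destination correspondence pairs")
  sets <- if (choose(n, 4) <= nSamples) combn(n, 4L) else
    withPrivateSeed(seed, vapply(seq_len(nSamples),
                                 function(i) sample.int(n, 4L),
                                 integer(4L)))
  best <- NULL; bestScore <- Inf
  for (k in seq_len(ncol(sets))) {
    s <- sets[, k]
    if (.degenerateQuad(src[s, , drop = FALSE]) ||
        .degenerateQuad(dst[s, , drop = FALSE])) next
    H <- .solveDLT(src[s, , drop = FALSE], dst[s, , drop = FALSE])
    if (is.null(H)) next
    score <- median(.squaredResiduals(H, src, dst))
    if (score < bestScore) { bestScore <- score; best <- H }
  }
  if (is.null(best))
    .stopf("degenerate correspondence configuration: no valid minimal sample")
  sigma <- 1.4826 * (1 + 5 / (n - 4)) * sqrt(bestScore)
  inliers <- sqrt(.squaredResiduals(best, src, dst)) <= 2.5 * sigma + 1e-8
  refit <- .solveDLT(src[inliers, , drop = FALSE],
                     dst[inliers, , drop = FALSE])
  if (!is.null(refit)) best <- refit
  new("Homography", H = best, inliers = inliers, medianResidual = bestScore)
}

#' Apply a homography to distance-plane points
#'
#' Homogeneous transform with perspective division, taking distance-plane
#' (x, y) in metres to plan coordinates in millimetres.
#'
#' @param points n x 2 matrix (or numeric(2)) of distance-plane points
#' @param H a \linkS4class{Homography} or a plain 3 x 3 matrix
#' @return an n x 2 matrix of plan points (mm)
#' @export
toPlan <- function(points, H) {
  if (is(H, "Homography")) H <- H@H
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  p <- cbind(points, 1) %*% t(H)
  if (any(abs(p[, 3]) < 1e-12))
    .stopf("point maps to infinity (homogeneous w ~ 0)")
  cbind(x = p[, 1] / p[, 3], y = p[, 2] / p[, 3])
}

#' Allocate plan points to seats or the aisle
#'
#' Returns, for each plan point, the label of the seat polygon containing
#' it, \code{"aisle"} for the aisle polygon, or \code{"unallocated"} when
#' no polygon contains it. Excluded seats are never returned. Plan polygons
#' are interior-disjoint (validated at load time), so containment is
#' unambiguous up to boundaries; boundary points go to the first polygon in
#' label order (aisle last), deterministically.
#'
#' @param points n x 2 matrix (or numeric(2)) of plan points (mm)
#' @param plan a \linkS4class{SeatPlan}
#' @return a character vector of labels
#' @examples
#' plan <- busSeatPlan()
#' allocateSeat(seatAnchors(plan, "C4")[, c("x", "y")], plan)
#' @export
allocateSeat <- function(points, plan) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  labs <- sort(setdiff(names(seatPolygons(plan)), excludedSeats(plan)))
  out <- rep("unallocated", nrow(points))
  polys <- c(seatPolygons(plan)[labs], list(aisle = aislePolygon(plan)))
  for (nm in names(polys)) {
    todo <- out == "unallocated"
    if (!any(todo)) break
    p <- polys[[nm]]
    hit <- pracma::inpolygon(points[todo, 1], points[todo, 2],
                             p[, 1], p[, 2], boundary = TRUE)
    out[todo][hit] <- nm
  }
  out
}

#' Allocate every detection in a frame stream to a plan position
#'
#' Convenience wrapper running the full seat-mapping chain per detection:
#' depth lookup at the nose, distance-plane projection, homography to the
#' plan, and point-in-polygon allocation.
#'
#' @param frames list of preprocessed \linkS4class{FrameRecord}
#' @param intr a \linkS4class{CameraIntrinsics}
#' @param H a \linkS4class{Homography}
#' @param plan a \linkS4class{SeatPlan}
#' @param depthRange plausible depth range in metres
#' @return a data.frame: \code{frameId}, \code{timestamp},
#'   \code{detectionId}, \code{seat} (label, \code{"aisle"},
#'   \code{"unallocated"}, or \code{NA} for invalid depth)
#' @export
allocateDetections <- function(frames, intr, H, plan,
                               depthRange = c(0.3, 10)) {
  rows <- lapply(frames, function(fr) {
    dets <- fr@detections
    if (!length(dets)) return(NULL)
    nose <- t(vapply(dets, function(d) d@keypoints[1L, 1:2], numeric(2)))
    depth <- vapply(seq_len(nrow(nose)), function(i)
      depthAt(fr, nose[i, 1], nose[i, 2]), numeric(1))
    depth[!is.na(depth) &
          (depth < depthRange[1] | depth > depthRange[2])] <- NA
    seat <- rep(NA_character_, nrow(nose))
    ok <- !is.na(depth)
    if (any(ok)) {
      dp <- toDistancePlane(nose[ok, 1], nose[ok, 2], depth[ok], intr)
      seat[ok] <- allocateSeat(toPlan(dp, H), plan)
    }
    data.frame(frameId = fr@frameId, timestamp = fr@timestamp,
               detectionId = vapply(dets, function(d) d@detectionId,
                                    character(1)),
               seat = seat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frameId = character(), timestamp = .BASE_TIME[0],
                      detectionId = character(), seat = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Seat occupancy event series and percent of time occupied
#'
#' Turns per-frame seat allocations into, per plan position, a list of
#' occupied (start, end) intervals and the percent of recording time
#' occupied (occupied frames over all recorded frames). Interval merging
#' tolerates short dropout gaps: a run interrupted by at most
#' \code{gapTolerance} consecutive unoccupied frames is kept as one event.
#'
#' @param allocations data.frame from \code{\link{allocateDetections}}
#' @param frameTimes POSIXct vector of all recorded frame timestamps (the
#'   percent-of-time denominator), in capture order
#' @param gapTolerance maximum number of consecutive missing frames bridged
#'   within one occupancy event (default 1)
#' @return a list with \code{events} (data.frame seat, start, end, frames)
#'   and \code{percent} (data.frame seat, occupiedFrames, percent)
#' @export
occupancySeries <- function(allocations, frameTimes, gapTolerance = 1L) {
  if (is.unsorted(frameTimes))
    .stopf("frame timestamps must be in non-decreasing order")
  nFrames <- length(frameTimes)
  keys <- sort(unique(allocations$seat[!is.na(allocations$seat) &
                                       allocations$seat != "unallocated"]))
  uniqTimes <- sort(unique(frameTimes))
  events <- list(); perc <- list()
  for (seat in keys) {
    tocc <- unique(allocations$timestamp[!is.na(allocations$seat) &
                                         allocations$seat == seat])
    idx <- sort(match(tocc, uniqTimes))
    occFrames <- length(idx)
    runs <- split(idx, cumsum(c(1, diff(idx) > gapTolerance + 1L)))
    for (r in runs)
      events[[length(events) + 1L]] <-
        data.frame(seat = seat, start = uniqTimes[min(r)],
                   end = uniqTimes[max(r)], frames = length(r),
                   stringsAsFactors = FALSE)
    perc[[length(perc) + 1L]] <-
      data.frame(seat = seat, occupiedFrames = occFrames,
                 percent = 100 * occFrames / nFrames,
                 stringsAsFactors = FALSE)
  }
  list(events = if (length(events)) do.call(rbind, events) else
         data.frame(seat = character(), start = .BASE_TIME[0],
                    end = .BASE_TIME[0], frames = integer()),
       percent = if (length(perc)) do.call(rbind, perc) else
         data.frame(seat = character(), occupiedFrames = integer(),
                    percent = numeric()))
}
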