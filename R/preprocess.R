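## Frame/detection hygiene filters, applied in the fixed order
## rotate -> de-duplicate -> low-confidence -> border -> masks.

#' Rotate a frame by 180 degrees
#'
#' The camera is mounted upside-down, so captured frames must be rotated
#' before analysis: depth values map as
#' \code{depth[i, j] -> depth[h-1-i, w-1-j]} and keypoints as
#' \code{(u, v) -> (w-1-u, h-1-v)}. A provenance flag guards against double
#' rotation.
#'
#' @param frame a \linkS4class{FrameRecord}
#' @param force apply even if the frame is already flagged rotated
#' @return the rotated \linkS4class{FrameRecord}
#' @export
rotate180 <- function(frame, force = FALSE) {
  if (frame@rotated && !force)
    .stopf("frame '%s' is already rotated (pass force = TRUE to override)",
           frame@frameId)
  d <- frame@depth
  h <- nrow(d); w <- ncol(d)
  frame@depth <- d[h:1, w:1, drop = FALSE]
  frame@detections <- lapply(frame@detections, function(det) {
    kp <- det@keypoints
    kp[, 1] <- (w - 1) - kp[, 1]
    kp[, 2] <- (h - 1) - kp[, 2]
    det@keypoints <- kp
    det
  })
  frame@rotated <- !frame@rotated
  frame
}

## MD5 of the raw 16-bit depth buffer, the frame's image byte-content.
.frameHash <- function(frame) {
  digest::digest(writeBin(as.vector(frame@depth), raw(), size = 2L),
                 algo = "md5", serialize = FALSE)
}

#' Remove exact duplicate frames
#'
#' Compares MD5 hashes of the raw depth buffers and keeps the first
#' occurrence of each byte-identical image, preserving stream order
#' (storage errors occasionally emit a frame twice).
#'
#' @param frames list of \linkS4class{FrameRecord}
#' @return the de-duplicated list, with attributes \code{removed} (count)
#'   and \code{removedIds} (frame ids dropped)
#' @export
dedupeExact <- function(frames) {
  hashes <- vapply(frames, .frameHash, character(1))
  dup <- duplicated(hashes)
  out <- frames[!dup]
  attr(out, "removed") <- sum(dup)
  attr(out, "removedIds") <- vapply(frames[dup], frameId, character(1))
  out
}

## Drop detections whose nose confidence falls below `threshold`.
.filterConfidence <- function(detections, threshold = 0.05) {
  keep <- vapply(detections, function(d) d@keypoints[1L, 3L] >= threshold,
                 logical(1))
  out <- detections[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Drop detections near the image border
#'
#' The stereo field-of-view mismatch leaves an invalid depth band around the
#' depth map, so detections whose nose keypoint lies within
#' \code{borderRadius} pixels of any image edge (Chebyshev margin,
#' boundary-exclusive: a nose exactly at the radius survives) are excluded.
#'
#' @param detections list of \linkS4class{DetectionRecord}
#' @param borderRadius margin in pixels (default 30)
#' @param imageSize integer(2): width, height
#' @return the surviving detections, with attribute \code{removed}
#' @export
filterBorder <- function(detections, borderRadius = 30, imageSize) {
  if (borderRadius < 0) .stopf("borderRadius must be >= 0")
  w <- imageSize[1]; h <- imageSize[2]
  if (2 * borderRadius >= min(w, h))
    .stopf("border radius %d leaves no valid region in a %dx%d image",
           borderRadius, w, h)
  keep <- vapply(detections, function(d) {
    u <- d@keypoints[1L, 1L]; v <- d@keypoints[1L, 2L]
    min(u, v, (w - 1) - u, (h - 1) - v) >= borderRadius
  }, logical(1))
  out <- detections[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Drop detections inside mask polygons
#'
#' Detections whose nose keypoint lies inside or on the boundary of any mask
#' polygon (handrails, reflective areas, depth shadows) are excluded.
#'
#' @param detections list of \linkS4class{DetectionRecord}
#' @param masks a \linkS4class{MaskSet}
#' @return the surviving detections, with attributes \code{removed} and
#'   \code{removedPerMask} (named drop counts)
#' @export
filterMasks <- function(detections, masks) {
  validObject(masks)
  perMask <- setNames(integer(length(masks@polygons)), names(masks@polygons))
  keep <- rep(TRUE, length(detections))
  for (i in seq_along(detections)) {
    nose <- detections[[i]]@keypoints[1L, ]
    for (nm in names(masks@polygons)) {
      p <- masks@polygons[[nm]]
      if (pracma::inpolygon(nose[1], nose[2], p[, 1], p[, 2],
                            boundary = TRUE)) {
        keep[i] <- FALSE
        perMask[nm] <- perMask[nm] + 1L
        break
      }
    }
  }
  out <- detections[keep]
  attr(out, "removed") <- sum(!keep)
  attr(out, "removedPerMask") <- perMask
  out
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: the 180-degree orientation fix (when frames are not
#' yet flagged rotated), exact-duplicate removal, the nose-confidence
#' filter, the border-margin filter, and the mask filter. Surviving records
#' are never modified, and re-applying the pipeline to its own output is a
#' no-op.
#'
#' @param frames list of \linkS4class{FrameRecord}
#' @param intr a \linkS4class{CameraIntrinsics} (for the image size)
#' @param masks a \linkS4class{MaskSet} or NULL
#' @param borderRadius border margin in pixels
#' @param confidenceThreshold minimum nose-keypoint confidence
#' @return a list with \code{frames} (filtered stream) and \code{log}, the
#'   per-stage accounting (frames in/out, duplicates removed, detections
#'   surviving each filter)
#' @examples
#' day <- simulateDay(scenarioConfig(seed = 1, duplicateFrameRate = 0.2),
#'                    duration = 1)
#' pre <- preprocessFrames(day$frames, busIntrinsics())
#' pre$log
#' @export
preprocessFrames <- function(frames, intr, masks = NULL, borderRadius = 30,
                             confidenceThreshold = 0.05) {
  imageSize <- c(intr@width, intr@height)
  frames <- lapply(frames, function(f) if (f@rotated) f else rotate180(f))
  frames <- dedupeExact(frames)
  log <- list(framesIn = length(frames) + attr(frames, "removed"),
              duplicatesRemoved = attr(frames, "removed"),
              duplicateIds = attr(frames, "removedIds"))
  nIn <- 0L; nConf <- 0L; nBorder <- 0L; nMask <- 0L
  perMask <- NULL
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    dets <- f@detections
    nIn <- nIn + length(dets)
    dets <- .filterConfidence(dets, confidenceThreshold)
    nConf <- nConf + length(dets)
    dets <- filterBorder(dets, borderRadius, imageSize)
    nBorder <- nBorder + length(dets)
    if (!is.null(masks)) {
      dets <- filterMasks(dets, masks)
      pm <- attr(dets, "removedPerMask")
      perMask <- if (is.null(perMask)) pm else perMask + pm
    }
    nMask <- nMask + length(dets)
    attributes(dets) <- NULL
    f@detections <- dets
    out[[i]] <- f
  }
  log$detectionsIn <- nIn
  log$afterConfidence <- nConf
  log$afterBorder <- nBorder
  log$afterMask <- nMask
  log$removedPerMask <- perMask
  log$framesOut <- length(out)
  list(frames = out, log = log)
}
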