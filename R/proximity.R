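## Per-frame pairwise distances and exposure statistics per occupancy level.

.BANDS <- c("LT1", "BT12", "GT2")

#' Risk band of a distance
#'
#' The three epidemiological distance categories partition the line:
#' \code{LT1} (< 1 m, increased risk), \code{BT12} (1-2 m inclusive,
#' moderate risk), \code{GT2} (> 2 m, lower risk). The boundary values 1 m
#' and 2 m fall in \code{BT12}, keeping the outer bands strictly "less
#' than" and "greater than" as labelled.
#'
#' @param m distances in metres (vectorised)
#' @return a factor with levels \code{LT1}, \code{BT12}, \code{GT2}
#' @examples
#' bandOf(c(0.5, 1, 1.7, 2, 2.5))
#' @export
bandOf <- function(m) {
  if (any(m < 0, na.rm = TRUE)) .stopf("distances must be non-negative")
  factor(ifelse(m < 1, "LT1", ifelse(m <= 2, "BT12", "GT2")),
         levels = .BANDS)
}

#' Occupancy level of a frame
#'
#' Detections as an integer percent of the visible seating capacity. With
#' the default capacity of 25 each passenger is exactly 4 percent, so
#' rounding is exact at every reachable count.
#'
#' @param n detection count(s)
#' @param capacity visible seating capacity (default 25)
#' @return integer percent(s), rounded half-up
#' @examples
#' occupancyLevel(9)    # 36
#' @export
occupancyLevel <- function(n, capacity = 25L) {
  if (any(n < 0)) .stopf("n must be >= 0")
  if (any(n > capacity))
    .stopf("detection count %d exceeds capacity %d (over-capacity frame)",
           max(n), capacity)
  as.integer(roundHalfUp(100 * n / capacity))
}

#' All pairwise nose-to-nose distances in a frame
#'
#' Measures the distance between every unordered pair of detections: the
#' nose keypoint's depth is looked up at the nearest pixel, scaled to
#' metres, and both noses deprojected to 3D before taking the Euclidean
#' distance. Pairs in which either depth is invalid (raw 0) or outside the
#' plausibility range are skipped and tallied, so that measured + skipped
#' always accounts for all C(n, 2) pair slots.
#'
#' @param frame a preprocessed \linkS4class{FrameRecord}
#' @param intr a \linkS4class{CameraIntrinsics}
#' @param depthRange plausible depth range in metres; lookups outside it
#'   are treated as invalid
#' @param medianFallback passed to \code{\link{depthAt}}
#' @return a list: \code{frameId}, \code{timestamp}, \code{n} (detection
#'   count), \code{pairs} (data.frame id0, id1, m), \code{skipped} (invalid
#'   pair count), \code{validIds} (detections with usable depth)
#' @export
allPairs <- function(frame, intr, depthRange = c(0.3, 10),
                     medianFallback = FALSE) {
  dets <- frame@detections
  n <- length(dets)
  ids <- vapply(dets, function(d) d@detectionId, character(1))
  nose <- t(vapply(dets, function(d) d@keypoints[1L, 1:2], numeric(2)))
  depth <- vapply(seq_len(n), function(i)
    depthAt(frame, nose[i, 1], nose[i, 2], medianFallback), numeric(1))
  valid <- !is.na(depth) & depth >= depthRange[1] & depth <= depthRange[2]
  pairs <- data.frame(id0 = character(), id1 = character(), m = numeric(),
                      stringsAsFactors = FALSE)
  skipped <- 0L
  if (n >= 2L) {
    cmb <- combn(n, 2L)
    okPair <- valid[cmb[1L, ]] & valid[cmb[2L, ]]
    skipped <- sum(!okPair)
    if (any(okPair)) {
      P <- matrix(NA_real_, n, 3L)
      P[valid, ] <- deprojectPixel(nose[valid, 1], nose[valid, 2],
                                   depth[valid], intr)
      i <- cmb[1L, okPair]; j <- cmb[2L, okPair]
      m <- sqrt(rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
      pairs <- data.frame(id0 = ids[i], id1 = ids[j], m = m,
                          stringsAsFactors = FALSE)
    }
  }
  list(frameId = frame@frameId, timestamp = frame@timestamp, n = n,
       pairs = pairs, skipped = skipped, validIds = ids[valid])
}

#' Measure all frames
#'
#' Applies \code{\link{allPairs}} to every frame. Frames with fewer than
#' two detections contribute occupancy information only.
#'
#' @param frames list of preprocessed \linkS4class{FrameRecord}
#' @inheritParams allPairs
#' @return a list of per-frame distance records
#' @export
measureFrames <- function(frames, intr, depthRange = c(0.3, 10),
                          medianFallback = FALSE) {
  lapply(frames, allPairs, intr = intr, depthRange = depthRange,
         medianFallback = medianFallback)
}

## Individuals qualifying for each band in one frame: a detection belongs
## to a band if at least one of its measured partners is at a band
## distance; one occurrence is enough, and bands are not exclusive.
.frameIndividuals <- function(fd) {
  bands <- bandOf(fd$pairs$m)
  lapply(setNames(.BANDS, .BANDS), function(b) {
    sel <- bands == b
    unique(c(fd$pairs$id0[sel], fd$pairs$id1[sel]))
  })
}

#' Exposure statistics per occupancy level
#'
#' Aggregates per-frame distance records into the risk summary: for each
#' occupancy level, the number of analysed images and, per risk band, the
#' total instance count, the mean instances per image, and the individual
#' likelihood — the mean over images of the fraction of individuals having
#' at least one other passenger at a band distance. Only frames with at
#' least two detections are analysed; individuals with no valid measurement
#' to anyone are excluded from a frame's denominator. With
#' \code{weighting = "pooled"} the likelihood is instead the pooled ratio
#' of qualifying individuals over all images at the level.
#'
#' @param frameDistances list of records from \code{\link{measureFrames}}
#' @param capacity occupancy denominator (default 25)
#' @param weighting \code{"per_image"} (default, images weighted equally)
#'   or \code{"pooled"}
#' @return a \linkS4class{RiskSummary}
#' @export
riskSummary <- function(frameDistances, capacity = 25L,
                        weighting = c("per_image", "pooled")) {
  weighting <- match.arg(weighting)
  if (length(frameDistances) == 0L) .stopf("no frames to summarise")
  analysed <- Filter(function(fd) fd$n >= 2L, frameDistances)
  if (length(analysed) == 0L)
    .stopf("no frames with at least two detections")
  levels <- vapply(analysed, function(fd) occupancyLevel(fd$n, capacity),
                   integer(1))
  perFrame <- lapply(analysed, function(fd) {
    counts <- table(bandOf(fd$pairs$m))
    quals <- .frameIndividuals(fd)
    denom <- length(fd$validIds)
    list(counts = as.numeric(counts[.BANDS]),
         nQual = vapply(quals, length, integer(1)),
         denom = denom)
  })
  levs <- sort(unique(levels))
  rows <- list()
  imgs <- integer(length(levs))
  for (li in seq_along(levs)) {
    sel <- which(levels == levs[li])
    imgs[li] <- length(sel)
    counts <- rowSums(vapply(perFrame[sel], `[[`, numeric(3), "counts"))
    nQual <- vapply(perFrame[sel], `[[`, numeric(3), "nQual")
    denom <- vapply(perFrame[sel], `[[`, numeric(1), "denom")
    like <- if (weighting == "per_image") {
      ok <- denom > 0
      if (any(ok)) rowMeans(nQual[, ok, drop = FALSE] /
                            rep(denom[ok], each = 3L)) else rep(NA_real_, 3L)
    } else {
      if (sum(denom) > 0) rowSums(nQual) / sum(denom) else rep(NA_real_, 3L)
    }
    rows[[li]] <- data.frame(level = levs[li], band = .BANDS,
                             total = counts, meanPerImage = counts / imgs[li],
                             likelihood = as.numeric(like),
                             stringsAsFactors = FALSE)
  }
  new("RiskSummary", capacity = as.integer(capacity), weighting = weighting,
      bands = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      imageCounts = data.frame(level = levs, images = imgs),
      analysedFrames = length(analysed),
      totalFrames = length(frameDistances))
}

#' Write the risk summary tables as CSV
#'
#' Emits the machine twins of the occupancy-level figures:
#' \code{risk_totals.csv} (level, band, total),
#' \code{risk_per_image.csv} (level, band, mean),
#' \code{risk_likelihood.csv} (level, band, likelihood) and
#' \code{image_distribution.csv} (level, images).
#'
#' @param summary a \linkS4class{RiskSummary}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeRiskTables <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- summary@bands
  write.csv(b[, c("level", "band", "total")],
            file.path(dir, "risk_totals.csv"), row.names = FALSE)
  write.csv(transform(b[, c("level", "band")], mean = b$meanPerImage),
            file.path(dir, "risk_per_image.csv"), row.names = FALSE)
  write.csv(b[, c("level", "band", "likelihood")],
            file.path(dir, "risk_likelihood.csv"), row.names = FALSE)
  write.csv(summary@imageCounts,
            file.path(dir, "image_distribution.csv"), row.names = FALSE)
  invisible(dir)
}
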