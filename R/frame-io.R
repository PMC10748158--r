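## On-disk frame exchange format: per-frame 16-bit grayscale TIFF depth,
## an 8-bit placeholder RGB PNG, a JSON sidecar (timestamp ISO-8601, depth
## scale S, rotation flag), a shared intrinsics.json, and keypoints as JSON
## Lines (one object per frame, detections as 17 x [u, v, confidence] in
## COCO order, pixels 0-based from the top-left).

.isoTime <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

#' Write / read a frame set directory
#'
#' @param frames list of \linkS4class{FrameRecord}
#' @param dir directory to write to (created if needed)
#' @param intr a \linkS4class{CameraIntrinsics} stored alongside the frames
#' @param rgbPlaceholder write a small placeholder RGB PNG per frame
#' @return \code{writeFrameSet}: \code{dir}, invisibly; \code{readFrameSet}:
#'   a list with elements \code{frames} and \code{intrinsics}
#' @export
writeFrameSet <- function(frames, dir, intr, rgbPlaceholder = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    width = intr@width, height = intr@height, fx = intr@fx, fy = intr@fy,
    cx = intr@cx, cy = intr@cy, distortion_model = intr@distortionModel,
    distortion_coeffs = intr@distortionCoeffs, hfov = intr@hfov,
    vfov = intr@vfov, depth_scale = intr@depthScale),
    file.path(dir, "intrinsics.json"), auto_unbox = TRUE, digits = NA)
  kpCon <- file(file.path(dir, "keypoints.jsonl"), "w")
  on.exit(close(kpCon))
  for (fr in frames) {
    id <- fr@frameId
    tiff::writeTIFF(fr@depth / 65535, file.path(dir, paste0(id, ".tif")),
                    bits.per.sample = 16L, compression = "none")
    if (rgbPlaceholder) {
      ph <- array(0.5, dim = c(48L, 64L, 3L))
      png::writePNG(ph, file.path(dir, paste0(id, ".png")))
    }
    jsonlite::write_json(list(frame_id = id,
                              timestamp = .isoTime(fr@timestamp),
                              depth_scale = fr@depthScale,
                              rotated = fr@rotated),
                         file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    dets <- lapply(fr@detections, function(d)
      list(id = d@detectionId, keypoints = unname(d@keypoints)))
    writeLines(jsonlite::toJSON(list(frame_id = id, detections = dets),
                                auto_unbox = TRUE, digits = NA), kpCon)
  }
  invisible(dir)
}

#' @rdname writeFrameSet
#' @export
readFrameSet <- function(dir) {
  ji <- jsonlite::fromJSON(file.path(dir, "intrinsics.json"))
  intr <- cameraIntrinsics(width = ji$width, height = ji$height,
                           fx = ji$fx, fy = ji$fy, cx = ji$cx, cy = ji$cy,
                           hfov = ji$hfov, vfov = ji$vfov,
                           distortionModel = ji$distortion_model,
                           distortionCoeffs = ji$distortion_coeffs,
                           depthScale = ji$depth_scale)
  kpLines <- readLines(file.path(dir, "keypoints.jsonl"))
  frames <- vector("list", length(kpLines))
  for (i in seq_along(kpLines)) {
    rec <- jsonlite::fromJSON(kpLines[i], simplifyMatrix = TRUE,
                              simplifyDataFrame = FALSE)
    id <- rec$frame_id
    side <- jsonlite::fromJSON(file.path(dir, paste0(id, ".json")))
    depth <- matrix(as.integer(roundHalfUp(
      tiff::readTIFF(file.path(dir, paste0(id, ".tif"))) * 65535)),
      nrow = intr@height, ncol = intr@width)
    dets <- lapply(rec$detections, function(d) {
      kp <- matrix(as.numeric(d$keypoints), ncol = 3L)
      dimnames(kp) <- list(.COCO_NAMES, c("u", "v", "confidence"))
      new("DetectionRecord", keypoints = kp, detectionId = d$id)
    })
    frames[[i]] <- new("FrameRecord", frameId = id,
                       timestamp = as.POSIXct(side$timestamp,
                                              format = "%Y-%m-%dT%H:%M:%OSZ",
                                              tz = "UTC"),
                       depth = depth, depthScale = side$depth_scale,
                       detections = dets, rotated = isTRUE(side$rotated))
  }
  list(frames = frames, intrinsics = intr)
}

#' Construct a mask set
#'
#' @param polygons named list of n x 2 matrices of (u, v) pixel vertices
#' @param imageSize integer(2): width, height
#' @return a \linkS4class{MaskSet}
#' @export
maskSet <- function(polygons = list(), imageSize = c(640L, 480L)) {
  polygons <- lapply(polygons, function(p) {
    m <- as.matrix(p); storage.mode(m) <- "double"
    colnames(m) <- c("u", "v"); m
  })
  new("MaskSet", polygons = polygons, imageSize = as.integer(imageSize))
}

#' Read / write mask polygons as JSON
#'
#' The JSON schema has an \code{image_size} [width, height] entry plus one
#' named entry per mask, each a list of [u, v] pixel vertices (0-based,
#' origin top-left, u = column).
#'
#' @param path file path
#' @param masks a \linkS4class{MaskSet}
#' @return \code{readMaskSet}: a \linkS4class{MaskSet}; \code{writeMaskSet}:
#'   \code{path}, invisibly
#' @export
readMaskSet <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  size <- as.integer(obj$image_size)
  obj$image_size <- NULL
  maskSet(lapply(obj, as.matrix), size)
}

#' @rdname readMaskSet
#' @export
writeMaskSet <- function(masks, path) {
  obj <- lapply(masks@polygons, unname)
  obj$image_size <- masks@imageSize
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read / write reference correspondences as CSV
#'
#' Columns: \code{u}, \code{v}, \code{depth_m}, \code{plan_x_mm},
#' \code{plan_y_mm}, \code{tag}.
#'
#' @param path file path
#' @param corr correspondences data.frame
#' @return \code{readCorrespondences}: the data.frame;
#'   \code{writeCorrespondences}: \code{path}, invisibly
#' @export
readCorrespondences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("u", "v", "depth_m", "plan_x_mm", "plan_y_mm")
  if (!all(need %in% names(df)))
    .stopf("correspondence file must have columns %s",
           paste(need, collapse = ", "))
  df
}

#' @rdname readCorrespondences
#' @export
writeCorrespondences <- function(corr, path) {
  write.csv(corr, path, row.names = FALSE)
  invisible(path)
}
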