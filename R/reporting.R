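## Run-level accounting and the end-to-end pipeline driver.

#' Build a cross-footed run report
#'
#' Assembles the run-level accounting summary and verifies its internal
#' consistency: the filter chain must be non-increasing, every pair slot
#' accounted for, and the allocation rate (seat/aisle allocations over
#' detections) well defined. With zero detections the rate is reported as
#' undefined (\code{NA}), not 0.
#'
#' @param preLog the \code{log} element of \code{\link{preprocessFrames}}
#' @param frameDistances list from \code{\link{measureFrames}}
#' @param allocations data.frame from \code{\link{allocateDetections}}
#' @return a \linkS4class{RunReport}
#' @export
buildReport <- function(preLog, frameDistances, allocations) {
  pairsMeasured <- sum(vapply(frameDistances, function(f) nrow(f$pairs),
                              integer(1)))
  pairsSkipped <- sum(vapply(frameDistances, function(f) f$skipped,
                             numeric(1)))
  slots <- sum(vapply(frameDistances, function(f) choose(f$n, 2),
                      numeric(1)))
  if (pairsMeasured + pairsSkipped != slots)
    .stopf("internal accounting error: %d measured + %d skipped != %d pair slots",
           pairsMeasured, pairsSkipped, slots)
  alloc <- sum(!is.na(allocations$seat) &
               allocations$seat != "unallocated")
  rate <- if (preLog$detectionsIn > 0) alloc / preLog$detectionsIn
          else NA_real_
  new("RunReport", frames = preLog$framesOut,
      duplicatesRemoved = preLog$duplicatesRemoved,
      detectionsIn = preLog$detectionsIn,
      afterConfidence = preLog$afterConfidence,
      afterBorder = preLog$afterBorder, afterMask = preLog$afterMask,
      pairsMeasured = pairsMeasured, pairsSkipped = pairsSkipped,
      allocations = alloc, allocationRate = rate)
}

.reportAsList <- function(report) {
  list(frames = report@frames,
       duplicates_removed = report@duplicatesRemoved,
       detections_in = report@detectionsIn,
       after_confidence = report@afterConfidence,
       after_border = report@afterBorder,
       after_mask = report@afterMask,
       pairs_measured = report@pairsMeasured,
       pairs_skipped = report@pairsSkipped,
       allocations = report@allocations,
       allocation_rate = if (is.na(report@allocationRate)) "undefined"
                         else round(report@allocationRate, 4),
       allocation_rate_percent = if (is.na(report@allocationRate)) "undefined"
         else as.integer(roundHalfUp(100 * report@allocationRate)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> measure -> risk summary -> seat
#' mapping -> report, writing every output table plus a JSON run report and
#' a plain-text log to \code{outDir}. Re-running with the same
#' configuration and seed byte-reproduces all outputs.
#'
#' Outputs written: \code{risk_totals.csv}, \code{risk_per_image.csv},
#' \code{risk_likelihood.csv}, \code{image_distribution.csv},
#' \code{seat_counts.csv}, \code{seat_percent.csv}, \code{events.csv},
#' \code{refs.csv}, \code{run_report.json}, \code{log.txt}, and (with
#' \code{keepFrames}) the simulated frame set under \code{frames/}.
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param outDir output directory (created if needed)
#' @param duration simulated duration in minutes (default a 60-minute
#'   service hour)
#' @param frameInterval capture cadence in seconds
#' @param masks optional \linkS4class{MaskSet}
#' @param keepFrames also write the simulated frame set to disk
#' @return invisibly, a list with all intermediate products:
#'   \code{day}, \code{pre}, \code{distances}, \code{risk}, \code{H},
#'   \code{allocations}, \code{occupancy}, \code{report}
#' @examples
#' \donttest{
#' res <- runAll(scenarioConfig(seed = 11), tempfile(), duration = 2)
#' res$report
#' }
#' @export
runAll <- function(config, outDir, duration = 60, frameInterval = 5,
                   masks = NULL, keepFrames = FALSE) {
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  intr <- config@intrinsics

  day <- simulateDay(config, duration, frameInterval)
  if (keepFrames)
    writeFrameSet(day$frames, file.path(outDir, "frames"), intr)
  pre <- preprocessFrames(day$frames, intr, masks)
  fd <- measureFrames(pre$frames, intr)
  risk <- riskSummary(fd, config@capacity)
  writeRiskTables(risk, outDir)

  corr <- referenceCorrespondences(config)
  writeCorrespondences(corr, file.path(outDir, "refs.csv"))
  src <- toDistancePlane(corr$u, corr$v, corr$depth_m, intr)
  H <- estimateHomography(src, cbind(corr$plan_x_mm, corr$plan_y_mm),
                          seed = config@seed)
  alloc <- allocateDetections(pre$frames, intr, H, config@seatPlan)
  frameTimes <- as.POSIXct(vapply(pre$frames,
                                  function(f) as.numeric(f@timestamp),
                                  numeric(1)),
                           origin = "1970-01-01", tz = "UTC")
  occ <- occupancySeries(alloc, frameTimes)

  counts <- as.data.frame(table(seat = alloc$seat[!is.na(alloc$seat)]),
                          stringsAsFactors = FALSE)
  names(counts) <- c("seat", "count")
  write.csv(counts, file.path(outDir, "seat_counts.csv"), row.names = FALSE)
  perc <- occ$percent
  perc$percent <- round(perc$percent, 2)
  write.csv(perc, file.path(outDir, "seat_percent.csv"), row.names = FALSE)
  ev <- occ$events
  ev$start <- .isoTime(ev$start); ev$end <- .isoTime(ev$end)
  write.csv(ev, file.path(outDir, "events.csv"), row.names = FALSE)

  report <- buildReport(pre$log, fd, alloc)
  jsonlite::write_json(c(.reportAsList(report),
                         list(seed = config@seed,
                              duration_min = duration,
                              frame_interval_s = frameInterval)),
                       file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("BusProximity %s",
                       as.character(utils::packageVersion("BusProximity"))),
               sprintf("seed: %d", config@seed),
               sprintf("duration_min: %g", duration),
               sprintf("frame_interval_s: %g", frameInterval),
               sprintf("frames: %d", length(day$frames)),
               sprintf("duplicates_removed: %d", pre$log$duplicatesRemoved),
               sprintf("detections: %d -> %d -> %d -> %d",
                       pre$log$detectionsIn, pre$log$afterConfidence,
                       pre$log$afterBorder, pre$log$afterMask),
               sprintf("pairs_measured: %d", as.integer(report@pairsMeasured)),
               sprintf("allocations: %d", as.integer(report@allocations))),
             file.path(outDir, "log.txt"))
  invisible(list(day = day, pre = pre, distances = fd, risk = risk,
                 H = H, allocations = alloc, occupancy = occ,
                 report = report))
}
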