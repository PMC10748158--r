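## Bus floor plan: labelled seat polygons in plan millimetres.

.rectPoly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

#' Construct a seat plan
#'
#' @param seats named list of n x 2 polygon matrices (plan mm)
#' @param aisle n x 2 polygon matrix for the aisle
#' @param excluded seat labels excluded from allocation
#' @return a \linkS4class{SeatPlan}
#' @export
seatPlan <- function(seats, aisle, excluded = character()) {
  seats <- lapply(seats, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "double"; p
  })
  aisle <- as.matrix(aisle); storage.mode(aisle) <- "double"
  new("SeatPlan", seats = seats, aisle = aisle, excluded = excluded)
}

#' Default single-decker bus seat plan
#'
#' The 25 seating positions visible to the ceiling camera: rows A-F front to
#' back by columns 1-4 offside to nearside, plus FM, the middle seat of the
#' back row, sitting over the aisle column. Columns 1-2 are offside
#' (window/aisle), columns 3-4 nearside (aisle/window). Nine positions where
#' detections are unreliable (poor visibility towards the back of the
#' vehicle, obstructions) are excluded from allocation by default.
#'
#' Geometry: the bus interior is 2.4 m wide; seats are 450 mm wide and 720 mm
#' deep with a 600 mm aisle; row A starts 1 m behind the camera bulkhead
#' (plan origin, front-offside corner; x across the bus, y towards the back).
#'
#' @param excluded seat labels excluded from allocation; the default is the
#'   standard visibility-limited set
#' @return a \linkS4class{SeatPlan} with 25 seat polygons plus the aisle
#' @examples
#' plan <- busSeatPlan()
#' names(seatPolygons(plan))
#' excludedSeats(plan)
#' @export
busSeatPlan <- function(excluded = c("A1", "D2", "D3", "E2", "E3",
                                     "F1", "F2", "F3", "F4")) {
  colX <- list(`1` = c(0, 450), `2` = c(450, 900),
               `3` = c(1500, 1950), `4` = c(1950, 2400))
  rowY0 <- 1000; pitch <- 720
  seats <- list()
  for (r in seq_along(LETTERS[1:6])) {
    row <- LETTERS[r]
    y0 <- rowY0 + (r - 1) * pitch
    for (cn in names(colX)) {
      xr <- colX[[cn]]
      seats[[paste0(row, cn)]] <- .rectPoly(xr[1], y0, xr[2], y0 + pitch)
    }
  }
  fy0 <- rowY0 + 5 * pitch
  seats[["FM"]] <- .rectPoly(900, fy0, 1500, fy0 + pitch)
  aisle <- .rectPoly(900, 0, 1500, fy0)
  seatPlan(seats, aisle, excluded)
}

#' Seat anchor points
#'
#' The plan-coordinate centroid of each seat polygon: the nominal (x, y)
#' position of a seated passenger's nose (its height above the floor is a
#' scenario parameter).
#'
#' @param plan a \linkS4class{SeatPlan}
#' @param seats labels to anchor; default all seats
#' @return a data.frame with columns \code{seat}, \code{x}, \code{y} (mm)
#' @export
seatAnchors <- function(plan, seats = names(seatPolygons(plan))) {
  cent <- t(vapply(seatPolygons(plan)[seats], polygonCentroid, numeric(2)))
  data.frame(seat = seats, x = cent[, 1], y = cent[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write a seat plan as JSON
#'
#' The JSON schema maps each seat label to a list of [x, y] vertex pairs in
#' plan millimetres, with special keys \code{"aisle"} (polygon) and
#' \code{"excluded"} (label array).
#'
#' @param path file path
#' @param plan a \linkS4class{SeatPlan}
#' @return \code{readSeatPlan}: a \linkS4class{SeatPlan};
#'   \code{writeSeatPlan}: \code{path}, invisibly
#' @export
readSeatPlan <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  excluded <- as.character(obj$excluded %||% character())
  aisle <- obj$aisle
  obj$excluded <- NULL; obj$aisle <- NULL
  seats <- lapply(obj, function(p) {
    m <- as.matrix(p); colnames(m) <- c("x", "y"); m
  })
  am <- as.matrix(aisle); colnames(am) <- c("x", "y")
  seatPlan(seats, am, excluded)
}

#' @rdname readSeatPlan
#' @export
writeSeatPlan <- function(plan, path) {
  obj <- lapply(seatPolygons(plan), function(p) unname(p))
  obj$aisle <- unname(aislePolygon(plan))
  obj$excluded <- excludedSeats(plan)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
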