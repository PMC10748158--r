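## Internal helpers shared across modules.

#' @importFrom methods new validObject slot is
#' @importFrom stats rnorm runif rexp median dpois setNames dist
#' @importFrom utils combn head write.csv read.csv
NULL

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards so package functions never perturb the
## global stream.
withPrivateSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Round half away from zero (base round() is banker's rounding).
roundHalfUp <- function(x) floor(x + 0.5)

## Segment intersection test used by the simple-polygon validity check.
## Segments (p1,p2) and (p3,p4), each a length-2 numeric. Proper crossings
## only; shared endpoints between adjacent edges are allowed by the caller.
.segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

## TRUE if the closed polygon (n x 2 matrix, vertices in order, not repeated)
## has no self-intersections between non-adjacent edges.
isSimplePolygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next    # first and last edges share a vertex
      if (.segmentsCross(poly[idx[i], ], poly[idx[i + 1L], ],
                         poly[idx[j], ], poly[idx[j + 1L], ]))
        return(FALSE)
    }
  }
  TRUE
}

## Signed polygon area (shoelace); used for centroids and overlap checks.
polygonArea <- function(poly) {
  x <- as.numeric(poly[, 1]); y <- as.numeric(poly[, 2])
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygonCentroid <- function(poly) {
  x <- as.numeric(poly[, 1]); y <- as.numeric(poly[, 2])
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- polygonArea(poly)
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

## Interior-overlap test between two simple polygons: any proper edge crossing,
## or one centroid strictly inside the other. Adequate for the convex,
## grid-aligned layouts used here.
.polygonsOverlap <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ia <- c(seq_len(na), 1L); ib <- c(seq_len(nb), 1L)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      if (.segmentsCross(a[ia[i], ], a[ia[i + 1L], ], b[ib[j], ], b[ib[j + 1L], ]))
        return(TRUE)
  ca <- polygonCentroid(a); cb <- polygonCentroid(b)
  if (pracma::inpolygon(ca[1], ca[2], b[, 1], b[, 2], boundary = FALSE)) return(TRUE)
  if (pracma::inpolygon(cb[1], cb[2], a[, 1], a[, 2], boundary = FALSE)) return(TRUE)
  FALSE
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
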