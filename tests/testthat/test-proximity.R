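## Hand-built per-frame distance record, mirroring measureFrames() output.
fdRecord <- function(n, m = numeric(), ids = paste0("p", seq_len(n)),
                     id0 = character(), id1 = character(), skipped = 0L,
                     frameId = "f") {
  list(frameId = frameId,
       timestamp = as.POSIXct("2021-05-10 09:00:00", tz = "UTC"),
       n = n,
       pairs = data.frame(id0 = id0, id1 = id1, m = m,
                          stringsAsFactors = FALSE),
       skipped = skipped, validIds = ids)
}

test_that("risk bands partition the line with closed middle interval", {
  expect_equal(as.character(bandOf(c(0, 0.5, 0.999, 1, 1.5, 2, 2.001, 2.5))),
               c("LT1", "LT1", "LT1", "BT12", "BT12", "BT12", "GT2", "GT2"))
  expect_error(bandOf(-0.1), "non-negative")
})

test_that("occupancy level is an integer percent of capacity", {
  expect_identical(occupancyLevel(9), 36L)
  expect_identical(occupancyLevel(0), 0L)
  expect_identical(occupancyLevel(14), 56L)
  expect_identical(occupancyLevel(25), 100L)
  expect_error(occupancyLevel(26), "exceeds capacity")
})

test_that("all pair slots are accounted for: measured plus skipped", {
  intr <- smallIntrinsics()
  d <- matrix(2000L, 120, 160)
  d[31, 21] <- 0L    # invalid depth at (u=20, v=30)
  mk <- function(n, invalidFirst = FALSE) {
    dets <- lapply(seq_len(n), function(i)
      makeDetection(20 + i * 4, 30, id = paste0("p", i)))
    if (invalidFirst) dets[[1]] <- makeDetection(20, 30, id = "p1")
    makeFrame(d, dets, id = paste0("n", n))
  }
  expect_equal(nrow(allPairs(mk(9), intr)$pairs), 36L)
  expect_equal(nrow(allPairs(mk(2), intr)$pairs), 1L)
  expect_equal(nrow(allPairs(mk(25), intr)$pairs), 300L)
  fd <- allPairs(mk(9, invalidFirst = TRUE), intr)
  expect_equal(fd$skipped, 8L)               # all pairs involving p1
  expect_equal(nrow(fd$pairs) + fd$skipped, choose(9, 2))
  expect_length(fd$validIds, 8L)
})

test_that("forced two-passenger frames give likelihood one in their band", {
  fds <- lapply(1:20, function(k)
    fdRecord(2, m = 0.5, id0 = "a", id1 = "b", ids = c("a", "b"),
             frameId = paste0("f", k)))
  rs <- riskSummary(fds, capacity = 25)
  tab <- riskTable(rs)
  expect_equal(tab$level, rep(8L, 3))
  expect_equal(tab$likelihood[tab$band == "LT1"], 1.0)
  expect_equal(tab$likelihood[tab$band == "BT12"], 0.0)
  expect_equal(tab$meanPerImage[tab$band == "LT1"], 1.0)
})

test_that("triangle frame matches the per-individual brute-force scan", {
  fd <- fdRecord(3, m = c(0.5, 1.5, 3.0),
                 id0 = c("p0", "p1", "p0"), id1 = c("p1", "p2", "p2"),
                 ids = c("p0", "p1", "p2"))
  rs <- riskSummary(list(fd), capacity = 25)
  tab <- riskTable(rs)
  expect_equal(tab$total, c(1, 1, 1))
  expect_equal(tab$likelihood[tab$band == "LT1"], 2 / 3)  # {p0, p1}
  expect_equal(tab$likelihood[tab$band == "BT12"], 2 / 3) # {p1, p2}
  expect_equal(tab$likelihood[tab$band == "GT2"], 2 / 3)  # {p0, p2}
})

test_that("band counts are conserved and totals cross-foot on synthetic data", {
  cfg <- smallScenario(seed = 27, arrivalRate = 2, dwellTime = 6)
  day <- simulateDay(cfg, duration = 45)
  pre <- preprocessFrames(day$frames, cfg@intrinsics)
  fds <- measureFrames(pre$frames, cfg@intrinsics)
  expect_gt(length(fds), 400L)
  for (fd in fds) {
    expect_equal(nrow(fd$pairs) + fd$skipped, choose(fd$n, 2))
    expect_equal(sum(table(bandOf(fd$pairs$m))), nrow(fd$pairs))
  }
  rs <- riskSummary(fds, cfg@capacity)
  tab <- riskTable(rs)
  imgs <- imageDistribution(rs)
  for (L in imgs$level) {
    sel <- tab$level == L
    expect_equal(tab$total[sel],
                 tab$meanPerImage[sel] * imgs$images[imgs$level == L],
                 tolerance = 1e-9)
  }
  expect_equal(sum(imgs$images), rs@analysedFrames)
})

test_that("summaries agree with an exhaustive recount on small frames", {
  set.seed(11)
  fds <- lapply(1:60, function(k) {
    n <- sample(2:6, 1)
    ids <- paste0("q", seq_len(n))
    cmb <- combn(n, 2)
    m <- runif(ncol(cmb), 0.2, 4)
    fdRecord(n, m = m, ids = ids,
             id0 = ids[cmb[1, ]], id1 = ids[cmb[2, ]],
             frameId = paste0("f", k))
  })
  rs <- riskSummary(fds, capacity = 25)
  tab <- riskTable(rs)
  ## brute-force recount, fully independent of the package's aggregation
  lims <- list(LT1 = c(-1, 1), BT12 = c(1, 2 + 1e-15), GT2 = c(2, Inf))
  for (band in names(lims)) {
    lo <- lims[[band]][1]; hi <- lims[[band]][2]
    inBand <- function(m) if (band == "BT12") m >= 1 & m <= 2 else
      if (band == "LT1") m < 1 else m > 2
    byLevel <- list()
    for (fd in fds) {
      L <- as.character(round(100 * fd$n / 25))
      qual <- 0
      for (id in fd$validIds) {
        ms <- fd$pairs$m[fd$pairs$id0 == id | fd$pairs$id1 == id]
        if (any(inBand(ms))) qual <- qual + 1
      }
      byLevel[[L]] <- c(byLevel[[L]], qual / fd$n)
    }
    for (L in names(byLevel)) {
      got <- tab$likelihood[tab$level == as.integer(L) & tab$band == band]
      expect_equal(got, mean(byLevel[[L]]), tolerance = 1e-12)
    }
  }
})

test_that("adding a passenger never removes an existing within-band partner", {
  ## exact nesting argument on fixed seatings: the qualifying set under k
  ## passengers is a subset of the qualifying set under k+1
  set.seed(12)
  intr <- busIntrinsics()
  for (rep in 1:20) {
    pos <- cbind(runif(8, -1, 1), runif(8, -0.3, 0.3), runif(8, 1, 5))
    qualSize <- function(k, band) {
      d <- as.matrix(dist(pos[seq_len(k), , drop = FALSE]))
      diag(d) <- NA
      sum(apply(d, 1, function(r) any(bandOf(r[!is.na(r)]) == band)))
    }
    for (band in c("LT1", "BT12"))
      for (k in 2:7)
        expect_gte(qualSize(k + 1, band), qualSize(k, band))
  }
})

test_that("within-band likelihoods rise with occupancy on simulated days", {
  cfg <- smallScenario(seed = 29, arrivalRate = 2, dwellTime = 2,
                       detectionDropout = 0)
  day <- simulateDay(cfg, duration = 60)
  pre <- preprocessFrames(day$frames, cfg@intrinsics)
  rs <- riskSummary(measureFrames(pre$frames, cfg@intrinsics), cfg@capacity)
  tab <- riskTable(rs)
  imgs <- imageDistribution(rs)
  ## restrict to well-sampled levels; statistical trend, not per-step
  keep <- imgs$level[imgs$images >= 20]
  for (band in c("BT12", "GT2")) {
    lk <- tab$likelihood[tab$band == band & tab$level %in% keep]
    expect_gt(cor(seq_along(lk), lk, method = "spearman"), 0)
    expect_gte(lk[length(lk)], lk[1])
  }
})

test_that("the 1-2 m annulus has three times the area of the <1 m disc", {
  th <- seq(0, 2 * pi, length.out = 4097)[-1]
  disc <- cbind(cos(th), sin(th))
  discArea <- abs(BusProximity:::polygonArea(disc))
  ann <- abs(BusProximity:::polygonArea(2 * disc)) - discArea
  expect_equal(ann / discArea, 3, tolerance = 1e-5)
})

test_that("pooled weighting is available and differs when images are unequal", {
  fds <- list(fdRecord(2, m = 0.5, id0 = "a", id1 = "b", ids = c("a", "b")),
              fdRecord(4, m = rep(3, 6),
                       id0 = c("a", "a", "a", "b", "b", "c"),
                       id1 = c("b", "c", "d", "c", "d", "d"),
                       ids = c("a", "b", "c", "d"), frameId = "g"))
  perImage <- riskTable(riskSummary(fds, weighting = "per_image"))
  pooled <- riskTable(riskSummary(fds, weighting = "pooled"))
  expect_equal(perImage$likelihood[perImage$band == "LT1" &
                                   perImage$level == 8], 1.0)
  expect_equal(pooled$likelihood[pooled$band == "LT1" &
                                 pooled$level == 8], 1.0)
})
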