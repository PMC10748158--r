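# BusProximity

Social distancing on public transport is hard to measure: on-board CCTV is
low-resolution, heavily distorted and monocular, so real distances between
passengers cannot be recovered from it. A single ceiling-mounted RGB-D
(stereo depth) camera changes that: given per-passenger pose keypoints and a
registered 16-bit depth frame, every passenger's nose can be placed in
metric 3D space, and the distances between all passengers — the quantity
that drives airborne-transmission risk — measured directly.

**BusProximity** implements that analysis chain end to end, in R, for
epidemiologists and transport researchers who need contact-exposure
statistics (for example as inputs to Quantitative Microbial Risk Assessment
models) and seat-level occupancy behaviour from depth-camera captures:

1. **Preprocessing** — 180° orientation fix for the inverted camera mount,
   MD5-based removal of byte-identical duplicate frames, exclusion of
   detections within a 30-pixel border margin (invalid stereo band), and
   exclusion of detections inside user-drawn mask polygons (handrails,
   reflective surfaces).
2. **Camera geometry** — depth lookup at the nose keypoint, scaling by the
   depth unit *S*, pinhole deprojection (with optional Brown–Conrady
   distortion) of pixel + depth to a 3D point *P(X, Y, Z)*, and the
   Euclidean nose-to-nose distance
   *m* = ‖*P*₀ − *P*₁‖ for **every pair** of passengers in a frame.
3. **Proximity analysis** — distances binned into the epidemiological risk
   bands **< 1 m** (increased risk), **1–2 m** (moderate), **> 2 m**
   (lower); per occupancy level (detections as a percent of the 25-seat
   visible capacity) the package reports total band counts, mean counts per
   image, and the *individual likelihood*: the mean over images of the
   fraction of individuals with at least one other passenger at a band
   distance.
4. **Seat mapping** — each deprojected point is reduced to a horizontal
   distance plane (range *r* = √(X² + Z²), bearing θ = *u*·HFOV/*w*), mapped
   onto a labelled bus floor plan by a 3×3 perspective transform *H*
   estimated with **least median of squares** (robust to up to half the
   reference correspondences being wrong), and allocated to seat/aisle
   polygons by point-in-polygon tests, yielding per-seat occupancy event
   series and percent-of-time-occupied tables.
5. **Synthetic scenes** — because real footage of identifiable passengers
   cannot be shared, a first-class generator simulates a service day:
   Poisson boarding / exponential dwell on a 25-position seat plan
   (rows A–F × columns 1–4 plus FM), rendered VGA depth frames with
   truncated-Gaussian depth noise, COCO 17-keypoint detections, detection
   dropout and duplicate-frame injection — with complete ground truth, so
   every stage of the pipeline is testable offline.

## Worked example

Simulate ten minutes of service, preprocess, measure all pairwise
distances, and summarise exposure per occupancy level:

```r
library(BusProximity)
cfg <- scenarioConfig(seed = 42)          # defaults: VGA camera, 25 seats
day <- simulateDay(cfg, duration = 10)    # 120 frames at one per 5 s
pre <- preprocessFrames(day$frames, cfg@intrinsics)
fds <- measureFrames(pre$frames, cfg@intrinsics)
riskSummary(fds)
#> RiskSummary (per_image): 120 analysed frames (>=2 detections) of 120, capacity 25
#>   level band total meanPerImage likelihood
#> 1     8  LT1     3    0.5000000  0.5000000
#> 2     8 BT12     1    0.1666667  0.1666667
#> 3     8  GT2     2    0.3333333  0.3333333
#> 4    12  LT1    43    0.9555556  0.6370370
#> 5    12 BT12    43    0.9555556  0.6148148
#> 6    12  GT2    49    1.0888889  0.6740741
#> ...
```

Read: at 12 % occupancy (three visible passengers) there were 45 analysed
images; a passenger had a 63.7 % chance of being within 1 m of at least one
other passenger, and the average image contained about one < 1 m pair.

Mapping the same detections onto the floor plan:

```r
corr <- referenceCorrespondences(cfg)     # 15 fixed interior features
H <- estimateHomography(
  toDistancePlane(corr$u, corr$v, corr$depth_m, cfg@intrinsics),
  cbind(corr$plan_x_mm, corr$plan_y_mm), seed = 43)
alloc <- allocateDetections(pre$frames, cfg@intrinsics, H, cfg@seatPlan)
table(alloc$seat)
#>  B1  B2  B4  C2  C3  C4  D1  FM
#> 115  20  70  94   2 115  36  34
buildReport(pre$log, fds, alloc)
#> RunReport
#>   frames: 120 (duplicates removed: 5)
#>   detections: 486 -> conf 486 -> border 486 -> mask 486
#>   pairs measured: 831, skipped (invalid depth): 0
#>   seat allocations: 486, allocation rate: 1.0000 (100%)
```

`runAll(cfg, "out/")` executes the whole chain and writes the CSV/JSON
artifact set (`risk_*.csv`, `seat_*.csv`, `events.csv`,
`run_report.json`), byte-reproducibly for a fixed seed. A thin CLI over
the same functions lives at `inst/cli/busprox.R`
(`busprox.R simulate|preprocess|measure|seats|run-all`).

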