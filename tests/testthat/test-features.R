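test_that("the circumcircle of three rim points is recovered exactly", {
  ar <- fitCircle(c(0, 0), c(2, 0), c(1, 1))
  expect_equal(arenaCentre(ar), c(1, 0))
  expect_equal(arenaRadius(ar), 1)
  expect_error(fitCircle(c(0, 0), c(1, 1), c(2, 2)),
               class = "ethotox_collinear")
  expect_error(fitCircle(c(0, 0), c(0, 0), c(2, 2)), "distinct")

  ## random points on a known circle
  set.seed(13)
  for (i in 1:5) {
    c0 <- runif(2, -50, 50); r0 <- runif(1, 10, 400)
    th <- sort(runif(3, 0, 2 * pi))
    pts <- lapply(th, function(a) c0 + r0 * c(cos(a), sin(a)))
    fit <- fitCircle(pts[[1]], pts[[2]], pts[[3]])
    expect_lt(max(abs(arenaCentre(fit) - c0)) / r0, 1e-9)
    expect_lt(abs(arenaRadius(fit) - r0) / r0, 1e-9)
  }
})

test_that("kinematics of scripted paths match closed forms", {
  ## stationary: 600 frames at 60 fps
  still <- scriptTrajectory(rep(100, 600), rep(100, 600))
  k <- kinematics(still)
  expect_equal(k$distance, 0)
  expect_equal(k$stopTime, 10)
  expect_equal(k$meanSpeed, 0)

  ## straight line at 1 px/frame: 0.055 mm * 60 Hz = 3.3 mm/s
  line <- scriptTrajectory(seq(0, 599), rep(0, 600))
  k2 <- kinematics(line)
  expect_equal(k2$meanSpeed, 3.3)
  expect_equal(k2$maxSpeed, 3.3)
  expect_equal(k2$meanAbsAcceleration, 0)
  expect_equal(k2$distance, 599 * 0.055)

  ## circular path: chord sum within 0.5% of the analytic arc length
  nsteps <- 600
  om <- 0.02
  ang <- om * (seq_len(nsteps) - 1)
  circ <- scriptTrajectory(500 + 100 * cos(ang), 500 + 100 * sin(ang))
  arc <- 100 * om * (nsteps - 1) * 0.055
  expect_lt(abs(kinematics(circ)$distance - arc) / arc, 0.005)

  expect_error(kinematics(scriptTrajectory(1, 1)), "2 frames")
})

test_that("zone membership splits time by the inner radius, boundary inward", {
  ar <- arenaGeometry(centre = c(0, 0), radius = 300, pxToMM = 0.055)
  th <- seq(0, 2 * pi, length.out = 120)
  orbit <- scriptTrajectory(0.9 * 300 * cos(th), 0.9 * 300 * sin(th))
  z <- zoneTimes(orbit, ar)
  expect_equal(z$outerTime, z$duration)
  expect_equal(z$innerTime, 0)

  centre <- scriptTrajectory(rep(0, 120), rep(0, 120))
  z2 <- zoneTimes(centre, ar)
  expect_equal(z2$innerTime, z2$duration)

  ## half in, half out by construction; a point exactly on the inner radius
  ## counts as inner
  half <- scriptTrajectory(c(rep(0, 30), rep(250, 30)), rep(0, 60))
  z3 <- zoneTimes(half, ar)
  expect_equal(z3$innerTime, z3$outerTime)
  onb <- scriptTrajectory(rep(200, 10), rep(0, 10))
  expect_equal(zoneTimes(onb, ar)$innerTime, 10 / 60)

  ## conservation
  expect_equal(z3$innerTime + z3$outerTime, z3$duration)

  ## far outside the dish: warned and clipped
  out <- scriptTrajectory(rep(400, 10), rep(0, 10))
  expect_warning(zoneTimes(out, ar), "clipped")
})

test_that("wall interactions count debounced entries into the 1 mm band", {
  ar <- arenaGeometry(centre = c(0, 0), radius = 300, pxToMM = 0.055)
  bandPx <- wallBandPx(ar)
  inside <- 150
  atWall <- 300 - bandPx / 2

  ## never near the wall
  w0 <- wallInteractions(scriptTrajectory(rep(inside, 50), rep(0, 50)), ar,
                         "body_centroid")
  expect_equal(w0$events, 0L)
  expect_equal(w0$contactTime, 0)

  ## exactly five entries, each dwelling 3 frames
  xs <- rep(inside, 100)
  starts <- c(10, 25, 40, 55, 70)
  for (s in starts) xs[s:(s + 2)] <- atWall
  w5 <- wallInteractions(scriptTrajectory(xs, rep(0, 100)), ar,
                         "body_centroid")
  expect_equal(w5$events, 5L)
  expect_equal(w5$contactTime, 15 / 60)

  ## single-frame jitter is debounced away
  xj <- rep(inside, 50); xj[20] <- atWall
  expect_equal(wallInteractions(scriptTrajectory(xj, rep(0, 50)), ar,
                                "body_centroid")$events, 0L)

  ## permanently in the band: one entry, full contact time
  wAll <- wallInteractions(scriptTrajectory(rep(atWall, 50), rep(0, 50)), ar,
                           "body_centroid")
  expect_equal(wAll$events, 1L)
  expect_equal(wAll$contactTime, wAll$duration)
})

test_that("body angles equal the quadrant-resolved arctangent in arena coords", {
  ## head right of back -> 0
  expect_equal(bodyAngles(data.frame(x = 1, y = 0),
                          data.frame(x = 0, y = 0))[1], 0)
  ## head above back in arena coordinates (smaller image y) -> pi/2
  expect_equal(bodyAngles(data.frame(x = 0, y = -1),
                          data.frame(x = 0, y = 0))[1], pi / 2)
  ## random geometry against the independent oracle
  set.seed(17)
  hx <- rnorm(50); hy <- rnorm(50); bx <- rnorm(50); by <- rnorm(50)
  a <- bodyAngles(data.frame(x = hx, y = hy), data.frame(x = bx, y = by))
  expected <- mapply(function(dy, dx) oracleAngle(dy, dx), -(hy - by), hx - bx)
  expect_equal(as.numeric(a), expected, tolerance = 1e-12)
  expect_true(all(a >= -pi & a <= pi))
  ## coincident points carry the previous angle forward and are flagged
  ac <- bodyAngles(data.frame(x = c(1, 0), y = c(0, 0)),
                   data.frame(x = c(0, 0), y = c(0, 0)))
  expect_equal(ac[2], ac[1])
  expect_identical(attr(ac, "degenerate"), 2L)
})

test_that("turning counts full rotations with correct chirality", {
  ## constant heading
  t0 <- turning(rep(0.3, 100))
  expect_identical(t0$leftTurns, 0L)
  expect_identical(t0$rightTurns, 0L)
  expect_equal(t0$cumulativeRotation, 0)

  ## three full counter-clockwise rotations
  ang <- wrapAng <- seq(0, 6 * pi, length.out = 601)
  ang <- atan2(sin(ang), cos(ang))  # normalized to [-pi, pi]
  t3 <- turning(ang)
  expect_identical(t3$leftTurns, 3L)
  expect_identical(t3$rightTurns, 0L)
  expect_equal(t3$cumulativeRotation, 6 * pi, tolerance = 1e-9)

  ## reversing the series swaps the counts
  tr <- turning(rev(ang))
  expect_identical(tr$leftTurns, t3$rightTurns)
  expect_identical(tr$rightTurns, t3$leftTurns)
  expect_equal(tr$cumulativeRotation, -t3$cumulativeRotation)
})

test_that("feature table separates the presets and keeps bookkeeping exact", {
  tbl <- cachedFeatureTable()
  expect_identical(nrow(tbl), 96L)
  expect_identical(sum(tbl$group == "control"), 32L)

  mdist <- tapply(tbl$distance, tbl$group, mean)
  expect_gt(mdist[["control"]], mdist[["lc10"]])
  expect_gt(mdist[["lc10"]], mdist[["lc30"]])

  ## conservation invariants on every row
  expect_equal(tbl$innerTime + tbl$outerTime, tbl$duration)
  expect_true(all(tbl$stopTime <= tbl$duration + 1e-9))
  expect_true(all(tbl$wallContactTime <= tbl$duration + 1e-9))
  expect_true(all(tbl$distance >= 0))
  expect_true(all(tbl$thigmoLeft >= 0 & tbl$thigmoRight >= 0))
})

test_that("a stationary individual yields zero motion features", {
  presets <- list(frozen = motionPreset("frozen", meanSpeed = 3, stopRate = 1,
                                        goRate = 0))
  coh <- makeCohort(groups = "frozen", sexes = "F", n = 1, nFrames = 300,
                    fps = 60, arena = bigDish(), seed = 5, presets = presets)
  tbl <- buildFeatureTable(coh)
  expect_equal(tbl$distance, 0)
  expect_equal(tbl$meanSpeed, 0)
  expect_equal(tbl$stopTime, tbl$duration)
  expect_equal(tbl$innerTime + tbl$outerTime, tbl$duration)
  expect_identical(tbl$leftTurns, 0L)
})

test_that("doubling the calibration doubles lengths but not counts or zones", {
  gt <- simulateTrajectory(motionPreset("control"), 600, 60, bigDish(),
                           seed = 91)
  traj1 <- truthTrajectory(gt)
  traj2 <- new("Trajectory", data = trajData(traj1), fps = 60,
               pxToMM = 2 * pxToMM(traj1))
  k1 <- kinematics(traj1); k2 <- kinematics(traj2)
  expect_equal(k2$distance, 2 * k1$distance)
  expect_equal(k2$meanSpeed, 2 * k1$meanSpeed)
  ## zone membership is a pure ratio: unchanged under recalibration of the
  ## same pixel data with a consistently rescaled arena
  ar1 <- bigDish()
  ar2 <- arenaGeometry(arenaCentre(ar1), arenaRadius(ar1),
                       pxToMM = 2 * pxToMM(ar1),
                       wallBandMM = 2 * ar1@wallBandMM)
  z1 <- zoneTimes(traj1, ar1); z2 <- zoneTimes(traj2, ar2)
  expect_equal(z1$innerTime, z2$innerTime)
  w1 <- wallInteractions(traj1, ar1, "antenna_R")
  w2 <- wallInteractions(traj2, ar2, "antenna_R")
  expect_identical(w1$events, w2$events)
  expect_equal(w1$contactTime, w2$contactTime)
})

test_that("feature table writer produces the CSV plus a units sidecar", {
  tbl <- cachedFeatureTable()[1:4, ]
  attr(tbl, "units") <- attr(cachedFeatureTable(), "units")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "features.csv")
  writeFeatureTable(tbl, path, config = list(fps = 60))
  expect_true(file.exists(path))
  side <- jsonlite::read_json(sub("csv$", "json", path))
  expect_equal(side$units$distance, "mm")
  back <- read.csv(path)
  expect_identical(nrow(back), 4L)
})
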