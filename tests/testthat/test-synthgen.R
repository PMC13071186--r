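test_that("an absorbing stop state freezes the walker with zero distance", {
  preset <- motionPreset("control", stopRate = 1, goRate = 0)
  gt <- simulateTrajectory(preset, nFrames = 50, fps = 60, arena = smallDish(),
                           seed = 3)
  tt <- truthTable(gt)
  expect_false(any(tt$moving))
  expect_equal(diff(range(tt$backX)), 0)
  expect_equal(diff(range(tt$backY)), 0)
  expect_equal(diff(range(tt$headX)), 0)
})

test_that("identical seeds reproduce trajectories bitwise, different seeds do not", {
  a <- simulateTrajectory(motionPreset("control"), 200, 60, smallDish(), seed = 9)
  b <- simulateTrajectory(motionPreset("control"), 200, 60, smallDish(), seed = 9)
  c <- simulateTrajectory(motionPreset("control"), 200, 60, smallDish(), seed = 10)
  expect_identical(truthTable(a), truthTable(b))
  expect_false(identical(truthTable(a), truthTable(c)))
})

test_that("empirical mean moving speed converges to the configured value", {
  ar <- bigDish()
  gt <- simulateTrajectory(motionPreset("control"), nFrames = 10000, fps = 60,
                           arena = ar, seed = 42)
  tt <- truthTable(gt)
  disp <- sqrt(diff(tt$backX)^2 + diff(tt$backY)^2)
  mmPerS <- disp * pxToMM(ar) * 60
  est <- mean(mmPerS[tt$moving[-1]])
  expect_lt(abs(est - 6.0) / 6.0, 0.05)
})

test_that("head and back centroids stay inside the arena for every preset", {
  ar <- smallDish()
  ctr <- arenaCentre(ar)
  for (lab in c("control", "lc10", "lc30")) {
    gt <- simulateTrajectory(motionPreset(lab), 2000, 60, ar, seed = 5)
    tt <- truthTable(gt)
    rho <- function(x, y) sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    expect_true(all(rho(tt$headX, tt$headY) <= arenaRadius(ar)), label = lab)
    expect_true(all(rho(tt$backX, tt$backY) <= arenaRadius(ar)), label = lab)
  }
})

test_that("treated presets have strictly lower configured speed and wall bias", {
  ctrl <- motionPreset("control")
  for (lab in c("lc10", "lc30")) {
    tr <- motionPreset(lab)
    expect_lt(tr@meanSpeed, ctrl@meanSpeed)
    expect_lt(tr@wallBias, ctrl@wallBias)
  }
  expect_lt(motionPreset("lc30")@meanSpeed, motionPreset("lc10")@meanSpeed)
})

test_that("preset validation rejects out-of-range rates", {
  expect_error(motionPreset("control", stopRate = 1.5), "0, 1")
  expect_error(motionPreset("control", meanSpeed = -1), "meanSpeed")
  expect_error(simulateTrajectory(motionPreset("control"), 100, fps = -1,
                                  arena = smallDish()), "fps")
  expect_error(simulateTrajectory(motionPreset("control"), 1, 60, smallDish()),
               "nFrames")
})

test_that("rendering without a body gives a uniform background", {
  gt <- simulateTrajectory(motionPreset("control"), 5, 60, smallDish(), seed = 1)
  fr <- renderFrame(gt, 0, noiseSd = 0, body = FALSE)
  expect_equal(length(unique(as.vector(fr$image))), 1L)
  expect_false(any(fr$mask))
})

test_that("silhouette area obeys inclusion-exclusion of the two lobes", {
  gt <- simulateTrajectory(motionPreset("control"), 5, 60, smallDish(), seed = 2)
  fr <- renderFrame(gt, 2, noiseSd = 0)
  overlap <- sum(fr$headMask & fr$backMask)
  expect_identical(sum(fr$mask),
                   sum(fr$headMask) + sum(fr$backMask) - overlap)
  expect_gt(overlap, 0)  # single connected body
})

test_that("the head lobe is smaller than the back lobe for every preset", {
  for (lab in c("control", "lc10", "lc30")) {
    gt <- simulateTrajectory(motionPreset(lab), 3, 60, smallDish(), seed = 4)
    fr <- renderFrame(gt, 1, noiseSd = 0)
    expect_lt(sum(fr$headMask), sum(fr$backMask))
  }
})

test_that("antenna tips sit anterior of the head along the body axis", {
  gt <- simulateTrajectory(motionPreset("control"), 100, 60, smallDish(),
                           seed = 6)
  tt <- truthTable(gt)
  u <- cbind(cos(tt$heading), sin(tt$heading))
  projL <- (tt$antLX - tt$headX) * u[, 1] + (tt$antLY - tt$headY) * u[, 2]
  projR <- (tt$antRX - tt$headX) * u[, 1] + (tt$antRY - tt$headY) * u[, 2]
  expect_true(all(projL > 0))
  expect_true(all(projR > 0))
})

test_that("cohort size equals the design product and cells are distinct", {
  coh <- makeCohort(groups = "control", sexes = "F", n = 1, nFrames = 5,
                    fps = 60, arena = smallDish(), seed = 1)
  expect_length(coh$individuals, 1L)

  coh2 <- makeCohort(groups = c("control", "lc30"), sexes = c("M", "F"), n = 2,
                     nFrames = 20, fps = 60, arena = smallDish(), seed = 8)
  expect_length(coh2$individuals, 8L)
  sers <- vapply(coh2$individuals,
                 function(i) paste(serialize(truthTable(i$truth), NULL),
                                   collapse = ""),
                 character(1))
  expect_identical(anyDuplicated(sers), 0L)

  ## reproducible under the master seed
  coh3 <- makeCohort(groups = c("control", "lc30"), sexes = c("M", "F"), n = 2,
                     nFrames = 20, fps = 60, arena = smallDish(), seed = 8)
  expect_identical(truthTable(coh2$individuals[[3]]$truth),
                   truthTable(coh3$individuals[[3]]$truth))
  expect_error(makeCohort(groups = character(0), arena = smallDish()), "empty")
})

test_that("ground truth round-trips through the CSV/JSON writers", {
  gt <- simulateTrajectory(motionPreset("control"), 10, 60, smallDish(),
                           seed = 3)
  dir <- withr::local_tempdir()
  paths <- writeGroundTruth(gt, dir)
  expect_true(all(file.exists(paths)))
  kp <- read.csv(paths[["keypoints"]])
  expect_setequal(unique(kp$part),
                  c("head", "back", "body_centroid", "antenna_L", "antenna_R"))
  ar <- jsonlite::read_json(paths[["arena"]])
  expect_equal(ar$radius, arenaRadius(smallDish()))
})
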