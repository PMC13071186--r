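test_that("threshold segmentation handles uniform frames and bad input", {
  expect_false(any(preprocessFrame(matrix(255, 40, 40))))
  expect_true(all(preprocessFrame(matrix(0, 40, 40))))
  expect_error(preprocessFrame(matrix(numeric(0), 0, 0)), "empty")
  expect_error(preprocessFrame(matrix(0, 4, 4), threshold = 300), "threshold")
  expect_error(preprocessFrame(matrix(0, 4, 4), blurKernel = 4), "odd")
})

test_that("segmentation of a rendered frame recovers the true silhouette", {
  gt <- simulateTrajectory(motionPreset("control"), 5, 60, smallDish(),
                           seed = 21)
  set.seed(1)
  fr <- renderFrame(gt, 1, noiseSd = 5)
  m <- preprocessFrame(fr$image)
  iou <- sum(m & fr$mask) / sum(m | fr$mask)
  expect_gte(iou, 0.9)
})

test_that("a pre-split mask needs zero erosions and assigns parts by area", {
  m <- matrix(FALSE, 30, 60)
  m[10:14, 5:14] <- TRUE        # 50 px blob
  m[6:15, 30:49] <- TRUE        # 200 px blob
  sp <- splitBody(m)
  expect_identical(sp$nErosions, 0L)
  expect_identical(sp$head$area, 50L)
  expect_identical(sp$back$area, 200L)
})

test_that("a dumbbell splits at the iteration where the bridge vanishes", {
  ## discs of radius 5 and 9 joined by a 3 px wide bridge
  m <- discMask(50, 80, 25, 15, 5) | discMask(50, 80, 25, 55, 9)
  m[24:26, 15:55] <- TRUE
  expect_identical(length(oracleComponents(m)), 1L)
  oracleIter <- oracleSplitIteration(m, maxIters = 10, minArea = 5)
  expect_false(is.na(oracleIter))
  sp <- splitBody(m, maxIters = 10, minArea = 5)
  expect_identical(sp$nErosions, as.integer(oracleIter))
  ## head is on the small-disc side, back on the large-disc side
  expect_lt(sp$head$centroid[1], 35)
  expect_gt(sp$back$centroid[1], 35)
  expect_lt(sp$head$area, sp$back$area)
})

test_that("a solid disc never splits within ten erosions", {
  m <- discMask(90, 90, 45, 45, 30)
  ## the oracle confirms the disc stays one component through 10 erosions
  expect_true(is.na(oracleSplitIteration(m, maxIters = 10, minArea = 5)))
  expect_error(splitBody(m, maxIters = 10), class = "ethotox_no_split")
  ## the axis-split fallback still yields two regions
  det <- labelFrame(255 * (1 - m), fallbackAxisSplit = TRUE)
  expect_setequal(det$part, c("head", "back"))
})

test_that("labelled head centroid matches ground truth within 3 px", {
  gt <- simulateTrajectory(motionPreset("control"), 10, 60, smallDish(),
                           seed = 31)
  tt <- truthTable(gt)
  set.seed(2)
  for (i in c(0, 4, 9)) {
    fr <- renderFrame(gt, i, noiseSd = 5)
    det <- labelFrame(fr$image)
    hc <- det[det$part == "head", ]
    err <- sqrt((hc$cx - tt$headX[i + 1])^2 + (hc$cy - tt$headY[i + 1])^2)
    expect_lt(err, 3)
    ## part boxes stay within the rendered silhouette bbox
    sil <- ethotox:::maskBBox(fr$mask)
    expect_gte(min(det$xmin), sil$xmin)
    expect_lte(max(det$xmax), sil$xmax)
    expect_true(all(det$area > 0))
  }
})

test_that("head/back assignment is orientation-free (180 degree rotation)", {
  gt <- simulateTrajectory(motionPreset("control"), 5, 60, smallDish(),
                           seed = 41)
  fr <- renderFrame(gt, 2, noiseSd = 0)
  det <- labelFrame(fr$image)
  rot <- fr$image[rev(seq_len(nrow(fr$image))), rev(seq_len(ncol(fr$image)))]
  detR <- labelFrame(rot)
  h <- det[det$part == "head", ]
  hR <- detR[detR$part == "head", ]
  w <- ncol(fr$image); hh <- nrow(fr$image)
  ## the head centroid maps to its point reflection
  expect_lt(abs(hR$cx - (w - 1 - h$cx)), 0.75)
  expect_lt(abs(hR$cy - (hh - 1 - h$cy)), 0.75)
  expect_identical(det$area, detR$area)
})

test_that("an exact area tie is broken deterministically and by motion", {
  img <- matrix(255, 40, 80)
  img[16:24, 11:19] <- 0    # two identical 9x9 squares
  img[16:24, 61:69] <- 0
  d1 <- labelFrame(img)
  d2 <- labelFrame(img)
  expect_identical(d1, d2)
  ## with motion toward +x the leading (right) square becomes the head
  dm <- labelFrame(img, motion = c(1, 0))
  expect_gt(dm[dm$part == "head", "cx"], dm[dm$part == "back", "cx"])
  dm2 <- labelFrame(img, motion = c(-1, 0))
  expect_lt(dm2[dm2$part == "head", "cx"], dm2[dm2$part == "back", "cx"])
})

test_that("erosion is monotone: foreground never grows across iterations", {
  set.seed(7)
  m <- discMask(60, 60, 30, 30, 20) | discMask(60, 60, 20, 40, 8)
  prev <- sum(m)
  cur <- m
  for (i in 1:5) {
    cur <- ethotox:::erodeMask(cur)
    expect_lte(sum(cur), prev)
    prev <- sum(cur)
  }
})

test_that("split counts follow floor allocation with remainder to train", {
  expect_identical(splitCounts(1200, c(0.7, 0.2, 0.1)),
                   c(train = 840L, val = 240L, test = 120L))
  expect_identical(splitCounts(10, c(1, 0, 0)),
                   c(train = 10L, val = 0L, test = 0L))
  expect_identical(sum(splitCounts(1234, c(0.7, 0.2, 0.1))), 1234L)
  expect_error(splitCounts(10, c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("dataset export writes annotations that round-trip within 0.5 px", {
  set.seed(3)
  n <- 40
  det <- do.call(rbind, lapply(0:(n - 1), function(f) {
    x0 <- runif(2, 10, 300); y0 <- runif(2, 10, 300)
    data.frame(frame = f, part = c("head", "back"),
               xmin = x0, ymin = y0, xmax = x0 + c(12, 25),
               ymax = y0 + c(10, 18),
               cx = x0 + c(6, 12.5), cy = y0 + c(5, 9),
               area = c(120, 450), confidence = 1)
  }))
  dir <- withr::local_tempdir()
  res <- exportDataset(det, dir, imageSize = c(400, 400), seed = 5)
  expect_identical(unname(res$counts), c(28L, 8L, 4L))
  expect_true(file.exists(file.path(dir, "classes.txt")))
  ann <- readAnnotation(file.path(dir, "labels", "frame_00000.txt"),
                        c(400, 400))
  orig <- det[det$frame == 0, ]
  expect_lt(max(abs(ann$cx - (orig$xmin + orig$xmax) / 2)), 0.5)
  expect_lt(max(abs(ann$cy - (orig$ymin + orig$ymax) / 2)), 0.5)
  expect_error(exportDataset(det, dir, c(400, 400), ratios = c(0.9, 0.2, 0.1)),
               "sum to 1")
})

test_that("detection evaluation scores a constructed error set exactly", {
  mkbox <- function(f, part, x, y, w = 10, h = 10, conf = 1)
    data.frame(frame = f, part = part, xmin = x, ymin = y, xmax = x + w,
               ymax = y + h, cx = x + w / 2, cy = y + h / 2, area = w * h,
               confidence = conf)
  truth <- rbind(mkbox(1, "head", 0, 0), mkbox(2, "head", 50, 50),
                 mkbox(3, "head", 100, 100), mkbox(4, "head", 150, 150),
                 mkbox(5, "head", 200, 200))
  ## 4 matched predictions, 2 false positives, 1 miss (frame 5)
  pred <- rbind(mkbox(1, "head", 1, 1), mkbox(2, "head", 51, 49),
                mkbox(3, "head", 99, 101), mkbox(4, "head", 150, 150),
                mkbox(2, "head", 300, 300, conf = 0.9),
                mkbox(3, "head", 400, 0, conf = 0.8))
  m <- evaluateDetection(pred, truth, iouThreshold = 0.5)
  pc <- m$perClass
  expect_identical(c(pc$TP, pc$FP, pc$FN), c(4L, 2L, 1L))
  expect_equal(pc$precision, 4 / 6)
  expect_equal(pc$recall, 4 / 5)
  expect_equal(pc$f1, 2 * (4 / 6) * (4 / 5) / (4 / 6 + 4 / 5))
  ## AP oracle: ranked by confidence the 4 TPs come first
  expect_equal(pc$ap, 4 / 5)
})

test_that("perfect predictions yield perfect metrics, and conventions hold", {
  gt <- simulateTrajectory(motionPreset("control"), 6, 60, smallDish(),
                           seed = 51)
  truth <- truthDetections(gt, 0:5)
  m <- evaluateDetection(truth, truth)
  expect_equal(m$overall$precision, 1)
  expect_equal(m$overall$recall, 1)
  expect_equal(m$overall$f1, 1)
  expect_equal(m$overall$map, 1)
  ## empty vs empty convention
  e <- evaluateDetection(truth[0, ], truth[0, ])
  expect_equal(e$overall$f1, 1)
  ## mismatched frame sets
  bad <- truth
  bad$frame <- bad$frame + 100
  expect_error(evaluateDetection(bad, truth), "missing")
  ## metric bounds on a noisy random set
  set.seed(9)
  jit <- truth
  jit$xmin <- jit$xmin + rnorm(nrow(jit), 0, 4)
  jit$xmax <- pmax(jit$xmax + rnorm(nrow(jit), 0, 4), jit$xmin + 1)
  mm <- evaluateDetection(jit, truth)
  vals <- unlist(mm$perClass[, c("precision", "recall", "accuracy", "f1", "ap")])
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("labelled frames always satisfy the head <= back area rule", {
  gt <- simulateTrajectory(motionPreset("lc10"), 20, 60, smallDish(),
                           seed = 61)
  set.seed(4)
  det <- labelFrames(function(i) renderFrame(gt, i - 1L, noiseSd = 5)$image,
                     n = 20)
  ok <- det$confidence > 0
  areas <- reshape(det[ok, c("frame", "part", "area")], idvar = "frame",
                   timevar = "part", direction = "wide")
  expect_true(all(areas$area.head <= areas$area.back))
})
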