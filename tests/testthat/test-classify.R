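sepData <- function(n = 32, d = 4, delta = 5, seed = 19) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, delta), n))
  list(x = x, y = rep(c("ctl", "trt"), each = n))
}

test_that("well-separated classes are classified almost perfectly", {
  dat <- sepData()
  for (m in c("svm", "rf", "knn")) {
    r <- nestedCV(dat$x, dat$y, model = m, seed = 3)
    expect_gte(r$metrics$accuracy, 0.95)
    expect_identical(sum(r$confusion), 64L)
  }
})

test_that("permuted labels score at chance level", {
  accs <- vapply(1:25, function(i) {
    set.seed(100 + i)
    x <- matrix(rnorm(64 * 4), 64)
    y <- sample(rep(c("a", "b"), each = 32))
    nestedCV(x, y, model = "knn", seed = i)$metrics$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("nested CV is deterministic under the seed", {
  dat <- sepData(n = 16, delta = 1)
  r1 <- nestedCV(dat$x, dat$y, model = "rf", seed = 11)
  r2 <- nestedCV(dat$x, dat$y, model = "rf", seed = 11)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$perFold, r2$perFold)
  r3 <- nestedCV(dat$x, dat$y, model = "rf", seed = 12)
  expect_false(identical(r1$outerFolds, r3$outerFolds))
})

test_that("stratification fails loudly when a class cannot fill the folds", {
  x <- matrix(rnorm(20 * 3), 20)
  y <- c(rep("a", 17), rep("b", 3))
  expect_error(nestedCV(x, y, model = "knn", kOuter = 4), "fewer samples")
  expect_error(nestedCV(x, rep("a", 20), model = "knn"), "binary")
})

test_that("confusion-matrix metrics follow the counting formulas", {
  m <- confusionMetrics(c(TP = 9, FN = 1, FP = 3, TN = 7))
  expect_equal(m$accuracy, 0.80)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.90)
  expect_equal(m$f1, 2 * 0.75 * 0.9 / (0.75 + 0.9))

  perfect <- confusionMetrics(matrix(c(10, 0, 0, 12), 2, 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b"))),
                              positive = "a")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  expect_warning(z <- confusionMetrics(c(TP = 0, FN = 5, FP = 0, TN = 5)),
                 "undefined")
  expect_true(is.nan(z$precision))
  expect_error(confusionMetrics(matrix(0, 2, 2)), "positive total")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(f1Score(0.78, 0.90), 2), 0.84)
  expect_equal(f1Score(1, 1), 1)
  expect_equal(f1Score(0, 0), 0)
  p <- runif(10); r <- runif(10)
  expect_true(all(f1Score(p, r) <= 2 * pmin(p, r)))
})

test_that("standardization is fitted on training data only (no leakage)", {
  set.seed(53)
  n <- 64
  y <- rep(c("a", "b"), each = n / 2)
  ## a sentinel feature equal to the label is learnable
  sentinel <- cbind(as.numeric(y == "b"), matrix(rnorm(n * 3), n))
  r <- nestedCV(sentinel, y, model = "knn", seed = 7)
  expect_gte(r$metrics$accuracy, 0.95)
  ## a constant feature (zero variance in any split) is harmless and useless
  const <- cbind(rep(1, n), matrix(rnorm(n * 3), n))
  r2 <- nestedCV(const, sample(y), model = "knn", seed = 7)
  expect_lte(r2$metrics$accuracy, 0.72)
})

test_that("grids default to the published search space, ordered simple-first", {
  g <- gridSpec()
  expect_setequal(g$svm$C, c(0.01, 0.1, 1, 10, 100))
  expect_setequal(g$rf$numTrees, c(20, 50, 100, 150, 200, 250, 300))
  expect_setequal(g$rf$maxDepth, 2:5)
  expect_setequal(g$knn$k, c(3, 5, 7, 9, 11, 13, 15))
  expect_identical(ethotox:::gridTable("knn", g)$k[1], 15)
  rf1 <- ethotox:::gridTable("rf", g)[1, ]
  expect_identical(c(rf1$numTrees, rf1$maxDepth), c(20, 2))
  svm1 <- ethotox:::gridTable("svm", g)[1, ]
  expect_identical(svm1$kernel, "linear")
  expect_identical(svm1$C, 0.01)
})

test_that("group comparison runs every requested model and validates pairs", {
  tbl <- cachedFeatureTable()
  res <- compareGroups(tbl, "control-lc30", models = c("svm", "rf", "knn"),
                       seed = 21, shapley = FALSE)
  expect_length(res$results, 3L)
  expect_setequal(names(res$results), c("svm", "rf", "knn"))
  expect_true(res$meanAccuracy > 0 && res$meanAccuracy <= 1)
  expect_error(compareGroups(tbl, "control-lc99"), "unknown group pair")
})

test_that("identical presets are indistinguishable (chance-level accuracy)", {
  ## two pseudo-groups drawn from the same preset
  coh <- makeCohort(groups = c("g1", "g2"), sexes = c("M", "F"), n = 8,
                    nFrames = 1200, fps = 60, arena = bigDish(), seed = 77,
                    presets = list(g1 = motionPreset("control"),
                                   g2 = motionPreset("control")))
  tbl <- buildFeatureTable(coh)
  res <- compareGroups(tbl, c("g1", "g2"), models = "knn", seed = 5,
                       shapley = FALSE)
  expect_lt(res$meanAccuracy, 0.72)
})

test_that("Shapley summary ranks locomotion features for separable groups", {
  tbl <- cachedFeatureTable()
  res <- compareGroups(tbl, c("control", "lc30"), models = "knn", seed = 9,
                       shapley = TRUE, backgroundCap = 32)
  expect_false(is.null(res$shap))
  expect_setequal(res$shap$feature, classifierFeatures())
  expect_true(all(res$shap$meanAbsShap >= 0))
  ## the strongly shifted locomotion features carry real attribution
  expect_gt(max(res$shap$meanAbsShap), 0.01)
})
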