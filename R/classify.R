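## Nested cross-validated classification of behavioural feature vectors:
## stratified 4x4 nested CV, grid-search hyperparameter selection by inner
## accuracy, pooled outer confusion matrix, and the binary group comparisons.

#' Hyperparameter grids
#'
#' Default search grids: SVM cost C on the decade ladder 0.01-100 with rbf
#' and linear kernels; random forest with 20-300 trees and maximum depth
#' 2-5; KNN with k in 3-15 (odd).
#'
#' @param svmC,svmKernel,rfTrees,rfDepth,knnK overrides for individual grids.
#' @return Named list of grids for models svm, rf, knn.
#' @export
gridSpec <- function(svmC = c(0.01, 0.1, 1, 10, 100),
                     svmKernel = c("linear", "rbf"),
                     rfTrees = c(20, 50, 100, 150, 200, 250, 300),
                     rfDepth = 2:5,
                     knnK = c(3, 5, 7, 9, 11, 13, 15)) {
  stopifnot(length(svmC) > 0, length(rfTrees) > 0, length(knnK) > 0)
  list(svm = list(C = svmC, kernel = svmKernel),
       rf = list(numTrees = rfTrees, maxDepth = rfDepth),
       knn = list(k = knnK))
}

## grid rows ordered simplest-first, so a stable which.max breaks accuracy
## ties toward the simpler model (smaller C / linear, fewer + shallower
## trees, larger k)
gridTable <- function(model, grid) {
  g <- grid[[model]]
  switch(model,
    svm = {
      tab <- expand.grid(kernel = g$kernel, C = sort(g$C),
                         stringsAsFactors = FALSE)
      tab[order(tab$C, match(tab$kernel, c("linear", "rbf"))),
          c("C", "kernel"), drop = FALSE]
    },
    rf = {
      tab <- expand.grid(maxDepth = sort(g$maxDepth),
                         numTrees = sort(g$numTrees))
      tab[order(tab$numTrees, tab$maxDepth), c("numTrees", "maxDepth"),
          drop = FALSE]
    },
    knn = data.frame(k = sort(g$k, decreasing = TRUE)),
    stop("unknown model: ", model, call. = FALSE)
  )
}

## column standardization fitted on training rows only; zero-sd columns are
## centred and left at zero deviation (no division blow-up)
standardizeFit <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

standardizeApply <- function(st, x) {
  scale(x, center = st$mean, scale = st$sd)[, , drop = FALSE]
}

## stratified k-fold assignment; error when a class has fewer members than
## folds (it would leave a class absent from some fold)
makeFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer samples (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fitPredict <- function(model, params, xtr, ytr, xte, seed = 1) {
  colnames(xtr) <- colnames(xte) <- paste0("f", seq_len(ncol(xtr)))
  switch(model,
    svm = {
      fit <- e1071::svm(x = xtr, y = ytr,
                        kernel = if (params$kernel == "rbf") "radial"
                                 else "linear",
                        cost = params$C, scale = FALSE)
      predict(fit, xte)
    },
    rf = {
      fit <- ranger::ranger(y = ytr, x = as.data.frame(xtr),
                            num.trees = params$numTrees,
                            max.depth = params$maxDepth,
                            seed = seed, num.threads = 1)
      predict(fit, data = as.data.frame(xte),
              num.threads = 1)$predictions
    },
    knn = {
      set.seed(seed)
      class::knn(xtr, xte, ytr, k = params$k, use.all = TRUE)
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

## inner grid search: mean accuracy over kInner stratified folds, ties to the
## first (simplest) grid row
innerSearch <- function(x, y, model, gridTab, kInner, seed) {
  set.seed(seed)
  folds <- makeFolds(y, kInner)
  acc <- numeric(nrow(gridTab))
  for (gi in seq_len(nrow(gridTab))) {
    hits <- 0L
    for (f in seq_len(kInner)) {
      tri <- folds != f
      st <- standardizeFit(x[tri, , drop = FALSE])
      pr <- fitPredict(model, gridTab[gi, , drop = FALSE],
                       standardizeApply(st, x[tri, , drop = FALSE]), y[tri],
                       standardizeApply(st, x[!tri, , drop = FALSE]),
                       seed = seed + gi)
      hits <- hits + sum(pr == y[!tri])
    }
    acc[gi] <- hits / length(y)
  }
  list(params = gridTab[which.max(acc), , drop = FALSE],
       innerAccuracy = max(acc))
}

#' Nested cross-validated classification
#'
#' Stratified outer folds estimate generalization; per outer-training set an
#' inner stratified CV grid search selects hyperparameters by mean inner
#' accuracy (ties to the simpler setting). Features are standardized with
#' parameters fitted on the respective training portion only (no leakage).
#' Outer-fold predictions are pooled into a single confusion matrix.
#' Deterministic under \code{seed}.
#'
#' @param x numeric feature matrix (rows = individuals).
#' @param y binary labels (coerced to factor).
#' @param model one of \code{"svm"}, \code{"rf"}, \code{"knn"}.
#' @param grid a \code{\link{gridSpec}}.
#' @param kOuter,kInner numbers of outer and inner folds (default 4 and 4).
#' @param seed integer seed controlling folds and learners.
#' @param positive positive class for the metrics (default: second factor
#'   level).
#' @return List of class \code{"cvResult"}: confusion (pooled), metrics
#'   (\code{\link{confusionMetrics}}), perFold (chosen hyperparameters),
#'   outerFolds, levels, model, seed.
#' @export
nestedCV <- function(x, y, model = c("svm", "rf", "knn"), grid = gridSpec(),
                     kOuter = 4, kInner = 4, seed = 1, positive = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop("labels must be binary", call. = FALSE)
  if (is.null(positive)) positive <- levels(y)[2]
  gridTab <- gridTable(model, grid)

  set.seed(as.integer(seed))
  outer <- makeFolds(y, kOuter)
  lv <- levels(y)
  conf <- matrix(0L, 2, 2, dimnames = list(truth = lv, predicted = lv))
  perFold <- vector("list", kOuter)
  for (o in seq_len(kOuter)) {
    tri <- outer != o
    pick <- innerSearch(x[tri, , drop = FALSE], y[tri], model, gridTab,
                        kInner, seed = (seed + 7919L * o) %% 2147483629L)
    st <- standardizeFit(x[tri, , drop = FALSE])
    pr <- fitPredict(model, pick$params,
                     standardizeApply(st, x[tri, , drop = FALSE]), y[tri],
                     standardizeApply(st, x[!tri, , drop = FALSE]),
                     seed = seed + o)
    conf <- conf + as.matrix(table(factor(y[!tri], levels = lv),
                                   factor(pr, levels = lv)))
    perFold[[o]] <- pick
  }
  structure(list(confusion = conf,
                 metrics = confusionMetrics(conf, positive = positive),
                 perFold = perFold, outerFolds = outer, levels = lv,
                 positive = positive, model = model, seed = seed),
            class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
  cat(sprintf("Nested CV (%s), %d samples, seed %d\n", x$model,
              sum(x$confusion), x$seed))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.3f precision %.3f recall %.3f F1 %.3f (positive: %s)\n",
              m$accuracy, m$precision, m$recall, m$f1, x$positive))
  invisible(x)
}

#' Binary group comparison with all classifiers and Shapley summary
#'
#' Runs \code{\link{nestedCV}} for each requested model on one binary group
#' pair of a feature table, aggregates mean accuracy/precision across
#' models, and (optionally) computes exact Shapley attributions for the KNN
#' model: per outer fold, the fold's selected k, a class-probability
#' prediction function (neighbourhood proportion of the positive class), the
#' fold's training portion as background (capped by seeded subsampling), and
#' the fold's test samples as explained instances.
#'
#' @param tbl feature table with a \code{group} column.
#' @param pair two group labels, or a single string like
#'   \code{"control-lc30"}.
#' @param models subset of c("svm", "rf", "knn").
#' @param grid a \code{\link{gridSpec}}.
#' @param seed integer seed.
#' @param features feature columns (default \code{\link{classifierFeatures}}).
#' @param shapley compute the KNN Shapley summary (default TRUE; requires
#'   "knn" in \code{models}).
#' @param backgroundCap max background rows per fold (default 64).
#' @return List of class \code{"groupClassification"}: results (per model
#'   cvResult), meanAccuracy, meanPrecision, shap (per-feature mean |phi|
#'   data.frame or NULL), pair.
#' @export
compareGroups <- function(tbl, pair, models = c("svm", "rf", "knn"),
                          grid = gridSpec(), seed = 1,
                          features = classifierFeatures(), shapley = TRUE,
                          backgroundCap = 64) {
  if (length(pair) == 1) pair <- strsplit(pair, "[-_]vs[-_]|-")[[1]]
  if (length(pair) != 2 || !all(pair %in% unique(tbl$group)))
    stop("unknown group pair: ", paste(pair, collapse = ", "), call. = FALSE)
  sub <- tbl[tbl$group %in% pair, , drop = FALSE]
  x <- as.matrix(sub[, features])
  y <- factor(sub$group, levels = pair)

  results <- lapply(models, function(m)
    nestedCV(x, y, model = m, grid = grid, seed = seed))
  names(results) <- models

  shap <- NULL
  if (shapley && "knn" %in% models) {
    res <- results[["knn"]]
    phiAll <- NULL
    for (o in seq_along(res$perFold)) {
      tri <- res$outerFolds != o
      st <- standardizeFit(x[tri, , drop = FALSE])
      xtr <- standardizeApply(st, x[tri, , drop = FALSE])
      xte <- standardizeApply(st, x[!tri, , drop = FALSE])
      k <- res$perFold[[o]]$params$k
      predFun <- knnProb(xtr, y[tri], k, positive = res$positive)
      set.seed(seed + 31L * o)
      bg <- xtr
      if (nrow(bg) > backgroundCap)
        bg <- bg[sample.int(nrow(bg), backgroundCap), , drop = FALSE]
      ex <- exactShapley(predFun, xte, bg)
      phiAll <- rbind(phiAll, ex$phi)
    }
    shap <- data.frame(feature = features,
                       meanAbsShap = colMeans(abs(phiAll)))
    shap <- shap[order(-shap$meanAbsShap), ]
    rownames(shap) <- NULL
  }
  structure(list(results = results,
                 meanAccuracy = mean(vapply(results, function(r)
                   r$metrics$accuracy, numeric(1))),
                 meanPrecision = mean(vapply(results, function(r)
                   r$metrics$precision, numeric(1))),
                 shap = shap, pair = pair, seed = seed),
            class = "groupClassification")
}

#' @export
print.groupClassification <- function(x, ...) {
  cat(sprintf("Group comparison %s vs %s: mean accuracy %.3f, mean precision %.3f\n",
              x$pair[1], x$pair[2], x$meanAccuracy, x$meanPrecision))
  for (m in names(x$results))
    cat(sprintf("  %-4s accuracy %.3f\n", m, x$results[[m]]$metrics$accuracy))
  if (!is.null(x$shap)) {
    cat("Top Shapley features (KNN):\n")
    print(head(x$shap, 5), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' KNN class-probability prediction function
#'
#' Returns a function mapping a feature matrix to the proportion of the k
#' nearest training neighbours belonging to the positive class — a
#' probability-like output suitable for Shapley attribution (hard labels
#' would make attributions step functions).
#'
#' @param train standardized training matrix.
#' @param cl training labels (factor).
#' @param k number of neighbours.
#' @param positive positive class (default: second level).
#' @return function(newdata matrix) -> numeric vector in [0, 1].
#' @export
knnProb <- function(train, cl, k, positive = levels(factor(cl))[2]) {
  train <- as.matrix(train)
  cl <- factor(cl)
  isPos <- cl == positive
  t2 <- rowSums(train^2)
  force(k)
  function(newdata) {
    newdata <- as.matrix(newdata)
    d2 <- outer(rowSums(newdata^2), t2, "+") - 2 * newdata %*% t(train)
    apply(d2, 1, function(r) mean(isPos[order(r)[seq_len(k)]]))
  }
}
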