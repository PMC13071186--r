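## Detection and classification performance metrics: IoU, greedy matching,
## per-class precision/recall/F1, average precision (all-point interpolation),
## mAP@0.5, and confusion-matrix metrics.

#' Intersection over union of two half-open boxes
#'
#' @param a,b numeric vectors (xmin, ymin, xmax, ymax), half-open.
#' @return IoU in [0, 1].
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 5, 15, 15))
#' @export
boxIoU <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  un <- areaA + areaB - inter
  if (un <= 0) return(0)
  inter / un
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in [0, 1].
#' @return F1 score.
#' @examples
#' f1Score(0.78, 0.90)
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

## Greedy matching of predictions to truth within one frame and class, by
## descending IoU; each truth box is matched at most once.
matchBoxes <- function(pred, truth, iouThreshold) {
  np <- nrow(pred); nt <- nrow(truth)
  matched <- logical(nt)
  tp <- logical(np)
  iouTP <- rep(NA_real_, np)
  if (np && nt) {
    iou <- matrix(0, np, nt)
    for (i in seq_len(np))
      for (j in seq_len(nt))
        iou[i, j] <- boxIoU(as.numeric(pred[i, c("xmin", "ymin", "xmax", "ymax")]),
                            as.numeric(truth[j, c("xmin", "ymin", "xmax", "ymax")]))
    ord <- order(iou, decreasing = TRUE)
    for (k in ord) {
      if (iou[k] < iouThreshold) break
      i <- (k - 1) %% np + 1
      j <- (k - 1) %/% np + 1
      if (!tp[i] && !matched[j]) {
        tp[i] <- TRUE
        matched[j] <- TRUE
        iouTP[i] <- iou[k]
      }
    }
  }
  list(tp = tp, matchedTruth = matched, iou = iouTP)
}

#' Evaluate part detections against ground truth
#'
#' Matches predictions to truth per frame and class, greedily by descending
#' IoU at the given threshold, and reports per-class and averaged detection
#' metrics: TP/FP/FN counts, precision, recall, accuracy
#' (TP / (TP + FP + FN); there are no true negatives in detection), F1, mean
#' IoU of matched pairs, per-class average precision (area under the
#' all-point-interpolated precision-recall curve, predictions ranked by
#' confidence), and mAP (mean AP over classes).
#'
#' When a frame set has no truth boxes and no predictions at all, metrics are
#' 1 by convention. Mismatched frame sets raise an error.
#'
#' @param pred,truth detection tables (frame, part, xmin, ymin, xmax, ymax,
#'   confidence); truth confidence is ignored.
#' @param iouThreshold IoU at which a matched prediction counts as TP
#'   (default 0.5).
#' @return A list of class \code{"detectionMetrics"}: \code{perClass}
#'   data.frame and \code{overall} (macro averages plus \code{map}).
#' @export
evaluateDetection <- function(pred, truth, iouThreshold = 0.5) {
  pred <- pred[!is.na(pred$xmin), , drop = FALSE]
  truth <- truth[!is.na(truth$xmin), , drop = FALSE]
  if (nrow(pred) == 0 && nrow(truth) == 0) {
    ones <- data.frame(part = "all", TP = 0, FP = 0, FN = 0, precision = 1,
                       recall = 1, accuracy = 1, f1 = 1, meanIoU = 1, ap = 1)
    out <- list(perClass = ones,
                overall = list(precision = 1, recall = 1, accuracy = 1,
                               f1 = 1, map = 1, iouThreshold = iouThreshold))
    class(out) <- "detectionMetrics"
    return(out)
  }
  extraPred <- setdiff(unique(pred$frame), unique(truth$frame))
  if (length(extraPred))
    stop("predicted frames missing from truth: ",
         paste(head(extraPred), collapse = ", "), call. = FALSE)
  classes <- sort(unique(c(pred$part, truth$part)))
  perClass <- lapply(classes, function(cl) {
    p <- pred[pred$part == cl, , drop = FALSE]
    t <- truth[truth$part == cl, , drop = FALSE]
    ## per-frame greedy matching
    recs <- data.frame(confidence = numeric(0), tp = logical(0),
                       iou = numeric(0))
    fn <- 0L
    for (f in sort(unique(c(p$frame, t$frame)))) {
      pf <- p[p$frame == f, , drop = FALSE]
      tf <- t[t$frame == f, , drop = FALSE]
      m <- matchBoxes(pf, tf, iouThreshold)
      fn <- fn + sum(!m$matchedTruth)
      if (nrow(pf))
        recs <- rbind(recs, data.frame(confidence = pf$confidence,
                                       tp = m$tp, iou = m$iou))
    }
    TP <- sum(recs$tp); FP <- sum(!recs$tp); FN <- fn
    precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    accuracy <- if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_
    data.frame(part = cl, TP = TP, FP = FP, FN = FN,
               precision = precision, recall = recall, accuracy = accuracy,
               f1 = f1Score(precision, recall),
               meanIoU = if (TP > 0) mean(recs$iou, na.rm = TRUE) else NA_real_,
               ap = averagePrecision(recs, TP + FN))
  })
  perClass <- do.call(rbind, perClass)
  overall <- list(precision = mean(perClass$precision, na.rm = TRUE),
                  recall = mean(perClass$recall, na.rm = TRUE),
                  accuracy = mean(perClass$accuracy, na.rm = TRUE),
                  f1 = mean(perClass$f1, na.rm = TRUE),
                  map = mean(perClass$ap, na.rm = TRUE),
                  iouThreshold = iouThreshold)
  out <- list(perClass = perClass, overall = overall)
  class(out) <- "detectionMetrics"
  out
}

## AP with all-point interpolation: rank by confidence (descending, stable),
## precision envelope integrated over recall.
averagePrecision <- function(recs, nTruth) {
  if (nTruth == 0) return(NA_real_)
  if (nrow(recs) == 0) return(0)
  ord <- order(-recs$confidence)
  tp <- cumsum(recs$tp[ord])
  fp <- cumsum(!recs$tp[ord])
  rec <- tp / nTruth
  prec <- tp / (tp + fp)
  ## precision envelope (monotone non-increasing from the right)
  env <- rev(cummax(rev(prec)))
  r <- c(0, rec)
  sum((r[-1] - r[-length(r)]) * env)
}

#' @export
print.detectionMetrics <- function(x, ...) {
  cat(sprintf("Detection metrics at IoU >= %.2f\n", x$overall$iouThreshold))
  print(x$perClass, row.names = FALSE, digits = 4)
  cat(sprintf("macro: precision %.3f recall %.3f F1 %.3f mAP %.3f\n",
              x$overall$precision, x$overall$recall, x$overall$f1,
              x$overall$map))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Standard binary metrics: accuracy (TP+TN)/(TP+TN+FP+FN), precision
#' TP/(TP+FP), recall TP/(TP+FN), and F1 as the harmonic mean of precision
#' and recall. Ratios with zero denominator are returned as NaN with a
#' warning.
#'
#' @param cm 2x2 confusion matrix with truth in rows and predictions in
#'   columns (same label order), or a named vector
#'   \code{c(TP = , FP = , FN = , TN = )}.
#' @param positive name of the positive class (default: first row name).
#' @return List with accuracy, precision, recall, f1 and the counts.
#' @examples
#' confusionMetrics(c(TP = 9, FN = 1, FP = 3, TN = 7))
#' @export
confusionMetrics <- function(cm, positive = NULL) {
  if (is.matrix(cm) || is.table(cm)) {
    cm <- as.matrix(cm)
    if (!all(dim(cm) == c(2, 2)) || any(cm < 0) || sum(cm) <= 0)
      stop("confusion matrix must be 2x2, non-negative, with positive total",
           call. = FALSE)
    if (is.null(positive)) positive <- rownames(cm)[1]
    pi <- match(positive, rownames(cm))
    if (is.na(pi)) stop("positive class not found", call. = FALSE)
    ni <- setdiff(1:2, pi)
    counts <- c(TP = cm[pi, pi], FP = cm[ni, pi],
                FN = cm[pi, ni], TN = cm[ni, ni])
  } else {
    counts <- cm[c("TP", "FP", "FN", "TN")]
    if (any(is.na(counts)) || any(counts < 0) || sum(counts) <= 0)
      stop("need non-negative TP/FP/FN/TN with positive total", call. = FALSE)
  }
  rat <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- rat(counts["TP"], counts["TP"] + counts["FP"], "precision")
  recall <- rat(counts["TP"], counts["TP"] + counts["FN"], "recall")
  list(accuracy = sum(counts[c("TP", "TN")]) / sum(counts),
       precision = unname(precision), recall = unname(recall),
       f1 = unname(f1Score(precision, recall)),
       counts = counts)
}
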