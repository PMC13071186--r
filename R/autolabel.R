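## Fully automatic head/back labelling: threshold segmentation of the dark
## insect, progressive morphological erosion until the body splits into two
## regions, area-based head/back assignment, and dataset export in the
## normalized detection-annotation text format.

noSplitError <- function(iters) {
  stop(structure(class = c("ethotox_no_split", "error", "condition"),
                 list(message = sprintf(
                   "body did not split into two regions within %d erosions",
                   iters),
                   call = NULL)))
}

noInsectError <- function() {
  stop(structure(class = c("ethotox_no_insect", "error", "condition"),
                 list(message = "no foreground object found", call = NULL)))
}

#' Segment the insect from a grey frame
#'
#' Gaussian blur followed by fixed-threshold binarization: foreground = pixels
#' darker than \code{threshold} (the insect is dark on a light background).
#' The blur sigma defaults to the common kernel-size rule
#' \code{0.3 * ((k - 1) / 2 - 1) + 0.8}.
#'
#' @param frame numeric matrix, grey levels 0-255 (row = y, column = x).
#' @param blurKernel odd spatial kernel size in px (default 5).
#' @param threshold binarization grey level in (0, 255) (default 60).
#' @param sigma Gaussian sigma; derived from \code{blurKernel} when NULL.
#' @return Logical foreground mask, same dimensions as \code{frame}.
#' @examples
#' img <- matrix(255, 32, 32); img[10:20, 12:22] <- 0
#' sum(preprocessFrame(img))
#' @export
preprocessFrame <- function(frame, blurKernel = 5, threshold = 60,
                            sigma = NULL) {
  if (length(frame) == 0) stop("empty image", call. = FALSE)
  if (threshold <= 0 || threshold >= 255)
    stop("threshold must lie in (0, 255)", call. = FALSE)
  if (blurKernel < 1 || blurKernel %% 2 != 1)
    stop("blurKernel must be odd and >= 1", call. = FALSE)
  if (blurKernel > 1) {
    if (is.null(sigma)) sigma <- 0.3 * ((blurKernel - 1) / 2 - 1) + 0.8
    kern <- EBImage::makeBrush(blurKernel, shape = "Gaussian", sigma = sigma)
    frame <- EBImage::filter2(frame, kern)
  }
  frame < threshold
}

## 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
## labels that touch diagonally with a small union-find.
labelComponents <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      while (parent[a] != a) a <- parent[a]
      while (parent[b] != b) b <- parent[b]
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

erodeMask <- function(mask) {
  out <- EBImage::erode(mask * 1L, EBImage::makeBrush(3, "box"))
  matrix(as.logical(round(out)), nrow(mask), ncol(mask))
}

## Components of a logical mask, ordered by decreasing area; each component is
## a list(pixels = 2-col matrix (row, col), area, centroid = c(x, y) 0-based).
componentList <- function(mask, minArea = 0) {
  lab <- labelComponents(mask)
  nl <- max(lab)
  if (nl == 0L) return(list())
  comps <- lapply(seq_len(nl), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    list(pixels = px, area = nrow(px),
         centroid = c(mean(px[, 2]) - 1, mean(px[, 1]) - 1))
  })
  comps <- Filter(function(cmp) cmp$area >= minArea, comps)
  comps[order(vapply(comps, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Split a body mask into head and back by progressive erosion
#'
#' Applies 0, 1, ..., \code{maxIters} erosions (3x3 square structuring
#' element) to the largest connected component until it falls apart into at
#' least two components above the minimum area floor. The two largest
#' resulting regions are returned, the smaller one as the head and the larger
#' as the back, with centroids computed on the eroded regions.
#'
#' @param mask logical foreground mask.
#' @param maxIters maximum number of erosion iterations (default 10).
#' @param minArea minimum component area in px^2 to count as a region
#'   (default 5; filters erosion debris).
#' @return A list with \code{head}, \code{back} (each: pixels, area, centroid),
#'   and \code{nErosions}. On equal areas, the assignment tie is broken by
#'   scan order (first-seen component becomes the head); callers tracking
#'   motion may re-assign.
#' @examples
#' m <- matrix(FALSE, 20, 40)
#' m[8:12, 3:10] <- TRUE    # small blob
#' m[5:15, 20:38] <- TRUE   # large blob
#' sp <- splitBody(m)
#' sp$nErosions; sp$head$area < sp$back$area
#' @export
splitBody <- function(mask, maxIters = 10, minArea = 5) {
  comps <- componentList(mask, minArea = 0)
  if (length(comps) == 0) noInsectError()
  ## operate on the largest component only
  cur <- matrix(FALSE, nrow(mask), ncol(mask))
  cur[comps[[1]]$pixels] <- TRUE
  others <- comps[-1]
  others <- Filter(function(cmp) cmp$area >= minArea, others)
  if (length(others) >= 1) {
    ## already >= 2 disjoint regions before any erosion
    two <- c(list(comps[[1]]), others)[1:2]
    return(assignHeadBack(two, nErosions = 0L))
  }
  for (it in 0:maxIters) {
    if (it > 0) cur <- erodeMask(cur)
    parts <- componentList(cur, minArea = minArea)
    if (length(parts) >= 2) return(assignHeadBack(parts[1:2], nErosions = it))
    if (length(parts) == 0) break
  }
  noSplitError(maxIters)
}

assignHeadBack <- function(two, nErosions) {
  a1 <- two[[1]]$area; a2 <- two[[2]]$area
  if (a1 == a2) {
    ## deterministic tie-break: first pixel in scan order leads
    ord <- order(vapply(two, function(cmp) {
      px <- cmp$pixels
      min((px[, 2] - 1) * 1e9 + px[, 1])
    }, numeric(1)))
    head <- two[[ord[1]]]; back <- two[[ord[2]]]
  } else if (a1 < a2) {
    head <- two[[1]]; back <- two[[2]]
  } else {
    head <- two[[2]]; back <- two[[1]]
  }
  list(head = head, back = back, nErosions = as.integer(nErosions))
}

#' Label head and back in one frame
#'
#' Full single-frame pipeline: segmentation (\code{\link{preprocessFrame}}),
#' crop to the insect bounding box, progressive-erosion split
#' (\code{\link{splitBody}}), then assignment of every pre-erosion body pixel
#' to the nearer eroded-region centroid (Voronoi assignment), so the part
#' bounding boxes cover the full lobes rather than the eroded cores. The
#' smaller assigned region is the head. On an exact area tie the component
#' whose centroid leads in the direction of \code{motion} (if given) becomes
#' the head.
#'
#' @param frame numeric grey matrix 0-255.
#' @param blurKernel,threshold,sigma passed to \code{\link{preprocessFrame}}.
#' @param maxIters,minArea passed to \code{\link{splitBody}}.
#' @param crop if TRUE (default), erosion operates on the insect-bbox crop.
#' @param motion optional unit vector (x, y) of recent motion for tie-breaks.
#' @param fallbackAxisSplit if TRUE, a body that never splits is divided by
#'   the line through its centroid perpendicular to its principal axis
#'   (default FALSE: a no-split frame raises the error the strict algorithm
#'   would).
#' @return A data.frame with one row per part (head, back): part, xmin, ymin,
#'   xmax, ymax (half-open, px, 0-based), cx, cy (eroded-core centroid), area
#'   (assigned full-body pixels), confidence.
#' @export
labelFrame <- function(frame, blurKernel = 5, threshold = 60, sigma = NULL,
                       maxIters = 10, minArea = 5, crop = TRUE, motion = NULL,
                       fallbackAxisSplit = FALSE) {
  mask <- preprocessFrame(frame, blurKernel, threshold, sigma)
  comps <- componentList(mask)
  if (length(comps) == 0) noInsectError()
  ## the insect is the largest component, or the two largest when the
  ## threshold already separates the lobes at the neck
  keep <- comps[1]
  if (length(comps) >= 2 && comps[[2]]$area >= minArea) keep <- comps[1:2]
  px <- do.call(rbind, lapply(keep, `[[`, "pixels"))
  if (crop) {
    pad <- 2L
    r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nrow(mask), max(px[, 1]) + pad)
    c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(ncol(mask), max(px[, 2]) + pad)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
    off <- c(c0 - 1L, r0 - 1L)  # (x, y) offset, 0-based
  } else {
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[px] <- TRUE
    off <- c(0L, 0L)
  }
  sp <- tryCatch(splitBody(sub, maxIters = maxIters, minArea = minArea),
                 ethotox_no_split = function(e) {
                   if (!fallbackAxisSplit) stop(e)
                   axisSplit(sub)
                 })
  cHead <- sp$head$centroid + off
  cBack <- sp$back$centroid + off
  ## Voronoi assignment of the full (pre-erosion) body pixels
  fx <- px[, 2] - 1; fy <- px[, 1] - 1
  dHead <- (fx - cHead[1])^2 + (fy - cHead[2])^2
  dBack <- (fx - cBack[1])^2 + (fy - cBack[2])^2
  isHead <- dHead < dBack
  partBox <- function(sel, centroid, part) {
    data.frame(part = part,
               xmin = min(fx[sel]), ymin = min(fy[sel]),
               xmax = max(fx[sel]) + 1, ymax = max(fy[sel]) + 1,
               cx = centroid[1], cy = centroid[2],
               area = sum(sel), confidence = 1)
  }
  areaHead <- sum(isHead); areaBack <- sum(!isHead)
  swap <- FALSE
  if (areaHead > areaBack) swap <- TRUE
  if (areaHead == areaBack && !is.null(motion)) {
    ## head leads in the direction of recent motion
    lead <- sum((cHead - cBack) * motion)
    if (lead < 0) swap <- TRUE
  }
  if (swap) {
    isHead <- !isHead
    tmp <- cHead; cHead <- cBack; cBack <- tmp
  }
  out <- rbind(partBox(isHead, cHead, "head"), partBox(!isHead, cBack, "back"))
  rownames(out) <- NULL
  out
}

## Fallback: split the un-eroded blob by the line through the centroid
## perpendicular to the principal axis.
axisSplit <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  x <- px[, 2] - 1; y <- px[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  cv <- stats::cov(cbind(x - cx, y - cy))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- (x - cx) * ev[1] + (y - cy) * ev[2]
  side <- proj >= 0
  mk <- function(sel) {
    list(pixels = px[sel, , drop = FALSE], area = sum(sel),
         centroid = c(mean(x[sel]), mean(y[sel])))
  }
  two <- list(mk(side), mk(!side))
  assignHeadBack(two[order(vapply(two, `[[`, numeric(1), "area"))],
                 nErosions = NA_integer_)
}

#' Label a sequence of frames
#'
#' Applies \code{\link{labelFrame}} to each frame; failed frames (no insect,
#' or no erosion split) are recorded with NA boxes. Recent motion from the
#' previous successful frame is used for area tie-breaks.
#'
#' @param frames list of grey matrices, or a function(i) returning frame i.
#' @param n number of frames when \code{frames} is a function.
#' @param ... passed to \code{\link{labelFrame}}.
#' @return A data.frame in the detection table layout with a \code{frame}
#'   column (0-based); failed frames appear with NA coordinates.
#' @export
labelFrames <- function(frames, n = length(frames), ...) {
  getFrame <- if (is.function(frames)) frames else function(i) frames[[i]]
  prevC <- NULL
  motion <- NULL
  out <- vector("list", n)
  for (i in seq_len(n)) {
    det <- tryCatch(labelFrame(getFrame(i), motion = motion, ...),
                    error = function(e) NULL)
    if (is.null(det)) {
      out[[i]] <- data.frame(frame = i - 1L, part = c("head", "back"),
                             xmin = NA_real_, ymin = NA_real_,
                             xmax = NA_real_, ymax = NA_real_,
                             cx = NA_real_, cy = NA_real_,
                             area = NA_real_, confidence = 0)
    } else {
      body <- c(mean(det$cx), mean(det$cy))
      if (!is.null(prevC)) {
        mv <- body - prevC
        nm <- sqrt(sum(mv^2))
        if (nm > 1e-9) motion <- mv / nm
      }
      prevC <- body
      out[[i]] <- cbind(frame = i - 1L, det)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allocate dataset split counts
#'
#' Floor allocation of \code{n} items to the given ratios with the remainder
#' assigned to the training split, so 1200 frames at 70:20:10 give exactly
#' 840/240/120.
#'
#' @param n number of items.
#' @param ratios numeric (train, val, test), non-negative, summing to 1.
#' @return Named integer vector (train, val, test).
#' @examples
#' splitCounts(1200, c(0.70, 0.20, 0.10))
#' @export
splitCounts <- function(n, ratios = c(0.70, 0.20, 0.10)) {
  if (any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be non-negative and sum to 1", call. = FALSE)
  cnt <- floor(n * ratios)
  cnt[1] <- cnt[1] + (n - sum(cnt))
  setNames(as.integer(cnt), c("train", "val", "test"))
}

#' Export a labelled detection dataset
#'
#' Writes one annotation text file per frame in the normalized detection
#' format ("class_id cx cy w h", coordinates in [0, 1] relative to the image
#' dimensions), a class-map file (head = 0, back = 1), and per-split manifest
#' files. Frames are assigned to train/val/test by a seeded shuffle with
#' floor allocation (remainder to train).
#'
#' @param detections detection table from \code{\link{labelFrames}} (columns
#'   frame, part, xmin, ymin, xmax, ymax); frames with NA boxes are skipped.
#' @param dir output directory.
#' @param imageSize \code{c(width, height)} of the frames, px.
#' @param ratios (train, val, test) ratios summing to 1.
#' @param seed shuffle seed.
#' @return Invisibly, a list with \code{counts} (train/val/test) and
#'   \code{splits} (frame id -> split).
#' @export
exportDataset <- function(detections, dir, imageSize,
                          ratios = c(0.70, 0.20, 0.10), seed = 1) {
  if (any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be non-negative and sum to 1", call. = FALSE)
  ok <- !is.na(detections$xmin)
  detections <- detections[ok, , drop = FALSE]
  frames <- sort(unique(detections$frame))
  n <- length(frames)
  cnt <- splitCounts(n, ratios)
  set.seed(as.integer(seed))
  shuffled <- sample(frames)
  split <- rep(c("train", "val", "test"), times = cnt)
  names(split) <- as.character(shuffled)

  labdir <- file.path(dir, "labels")
  dir.create(labdir, recursive = TRUE, showWarnings = FALSE)
  classId <- c(head = 0L, back = 1L)
  w <- imageSize[1]; h <- imageSize[2]
  for (f in frames) {
    rows <- detections[detections$frame == f, , drop = FALSE]
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     classId[rows$part],
                     (rows$xmin + rows$xmax) / 2 / w,
                     (rows$ymin + rows$ymax) / 2 / h,
                     (rows$xmax - rows$xmin) / w,
                     (rows$ymax - rows$ymin) / h)
    writeLines(lines, file.path(labdir, sprintf("frame_%05d.txt", f)))
  }
  writeLines(sprintf("%d %s", classId, names(classId)),
             file.path(dir, "classes.txt"))
  for (s in c("train", "val", "test")) {
    fs <- as.integer(names(split)[split == s])
    writeLines(sprintf("frame_%05d", sort(fs)),
               file.path(dir, paste0(s, ".txt")))
  }
  invisible(list(counts = cnt, splits = split))
}

#' Read an exported annotation file back into boxes
#'
#' Inverse of \code{\link{exportDataset}} for one frame: denormalizes the
#' "class_id cx cy w h" lines back to half-open pixel boxes.
#'
#' @param path annotation text file.
#' @param imageSize \code{c(width, height)} px.
#' @return data.frame with part, xmin, ymin, xmax, ymax, cx, cy.
#' @export
readAnnotation <- function(path, imageSize) {
  lines <- strsplit(readLines(path), " ")
  w <- imageSize[1]; h <- imageSize[2]
  out <- do.call(rbind, lapply(lines, function(v) {
    v <- as.numeric(v)
    cx <- v[2] * w; cy <- v[3] * h; bw <- v[4] * w; bh <- v[5] * h
    data.frame(part = c("head", "back")[v[1] + 1],
               xmin = cx - bw / 2, ymin = cy - bh / 2,
               xmax = cx + bw / 2, ymax = cy + bh / 2, cx = cx, cy = cy)
  }))
  out
}
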