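## Frame-by-frame tracking with the classical labeller, and trajectory
## conditioning: rolling-mean smoothing, low-pass speed filter, gap
## interpolation, central-segment extraction.

#' Tracking configuration
#'
#' @param fps acquisition rate, Hz (default 60).
#' @param pxToMM spatial calibration, mm/px (default 0.055).
#' @param smoothWindow odd rolling-mean window in frames (default 3).
#' @param speedCap low-pass speed threshold, mm/s; frame-to-frame speeds above
#'   it are treated as tracking errors (default 50).
#' @param stopSpeed stop-bout speed threshold, mm/s (default 0.5).
#' @param maxGap longest run of failed detections (frames) bridged by linear
#'   interpolation (default 5).
#' @param segmentStart,segmentDuration analysed segment in seconds; a NULL
#'   start means centre the segment in the recording (default: the central
#'   2 minutes).
#' @return A list of class \code{"trackingConfig"}.
#' @export
trackingConfig <- function(fps = 60, pxToMM = 0.055, smoothWindow = 3,
                           speedCap = 50, stopSpeed = 0.5, maxGap = 5,
                           segmentStart = NULL, segmentDuration = 120) {
  if (smoothWindow < 1 || smoothWindow %% 2 != 1)
    stop("smoothWindow must be odd and >= 1", call. = FALSE)
  if (!(speedCap > stopSpeed) || stopSpeed <= 0)
    stop("need speedCap > stopSpeed > 0", call. = FALSE)
  structure(list(fps = fps, pxToMM = pxToMM, smoothWindow = smoothWindow,
                 speedCap = speedCap, stopSpeed = stopSpeed, maxGap = maxGap,
                 segmentStart = segmentStart,
                 segmentDuration = segmentDuration),
            class = "trackingConfig")
}

#' Build a Trajectory from frames via the automatic labeller
#'
#' Runs \code{\link{labelFrame}} on every frame: head and back centroids per
#' frame, body centroid as their midpoint. Frames where labelling fails get
#' likelihood 0 and are linearly interpolated when the gap is at most
#' \code{maxGap} frames, else left missing (NA).
#'
#' @param frames list of grey matrices or a function(i) returning frame i.
#' @param config a \code{\link{trackingConfig}}.
#' @param n number of frames when \code{frames} is a function.
#' @param ... further arguments for \code{\link{labelFrame}}.
#' @return A \code{Trajectory} with parts head, back, body_centroid.
#' @export
trackVideo <- function(frames, config = trackingConfig(),
                       n = length(frames), ...) {
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  det <- labelFrames(frames, n = n, ...)
  ok <- det$confidence > 0
  if (!any(ok)) stop("labelling failed on every frame", call. = FALSE)
  mkSeries <- function(part) {
    d <- det[det$part == part, , drop = FALSE]
    d <- d[order(d$frame), ]
    x <- ifelse(d$confidence > 0, d$cx, NA_real_)
    y <- ifelse(d$confidence > 0, d$cy, NA_real_)
    lik <- ifelse(d$confidence > 0, 1, 0)
    x <- zoo::na.approx(x, maxgap = config$maxGap, na.rm = FALSE, rule = 1)
    y <- zoo::na.approx(y, maxgap = config$maxGap, na.rm = FALSE, rule = 1)
    data.frame(frame = d$frame, part = part, x = x, y = y, likelihood = lik)
  }
  hd <- mkSeries("head")
  bk <- mkSeries("back")
  bc <- data.frame(frame = hd$frame, part = "body_centroid",
                   x = (hd$x + bk$x) / 2, y = (hd$y + bk$y) / 2,
                   likelihood = pmin(hd$likelihood, bk$likelihood))
  new("Trajectory", data = rbind(hd, bk, bc), fps = config$fps,
      pxToMM = config$pxToMM)
}

#' Merge external keypoints (e.g. antenna tips) into a trajectory
#'
#' The classical labeller provides head/back only; antennal channels come
#' from an external keypoint table or from synthetic ground truth.
#'
#' @param traj a \code{Trajectory}.
#' @param keypoints data.frame (frame, part, x, y, likelihood).
#' @return The augmented \code{Trajectory}.
#' @export
addKeypoints <- function(traj, keypoints) {
  stopifnot(is(traj, "Trajectory"))
  if (is.null(keypoints$likelihood)) keypoints$likelihood <- 1
  new("Trajectory", data = rbind(trajData(traj),
                                 keypoints[, c("frame", "part", "x", "y",
                                               "likelihood")]),
      fps = trajFps(traj), pxToMM = pxToMM(traj))
}

## centred rolling mean with truncated windows at the ends, NA-tolerant
rollMeanTrunc <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Smooth a trajectory with a centred rolling mean
#'
#' Per part and coordinate; endpoints use truncated windows so the length is
#' preserved. Window 1 is the identity.
#'
#' @param traj a \code{Trajectory}.
#' @param window odd window length in frames (default 3).
#' @return The smoothed \code{Trajectory}.
#' @export
smoothTrajectory <- function(traj, window = 3) {
  stopifnot(is(traj, "Trajectory"))
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  d <- trajData(traj)
  for (p in unique(d$part)) {
    sel <- d$part == p
    ord <- order(d$frame[sel])
    idx <- which(sel)[ord]
    d$x[idx] <- rollMeanTrunc(d$x[idx], window)
    d$y[idx] <- rollMeanTrunc(d$y[idx], window)
  }
  new("Trajectory", data = d, fps = trajFps(traj), pxToMM = pxToMM(traj))
}

#' Low-pass speed filter
#'
#' Frame-to-frame speeds above \code{speedCap} are physiologically impossible
#' and treated as tracking errors: the offending target positions are removed
#' and re-interpolated linearly, and the number of corrected frames is
#' reported (attribute \code{"speedFlags"} on the result, also returned by
#' \code{speedFlags()}).
#'
#' @param traj a \code{Trajectory}.
#' @param speedCap threshold, mm/s; \code{Inf} disables the filter.
#' @param maxPasses safety bound on re-filtering passes (default 10).
#' @return The filtered \code{Trajectory} with attribute \code{speedFlags}.
#' @export
applySpeedFilter <- function(traj, speedCap = 50, maxPasses = 10) {
  stopifnot(is(traj, "Trajectory"))
  if (speedCap <= 0) stop("speedCap must be positive", call. = FALSE)
  d <- trajData(traj)
  capPx <- speedCap / pxToMM(traj) / trajFps(traj)  # px per frame
  flags <- 0L
  if (is.finite(capPx)) {
    for (p in unique(d$part)) {
      idx <- which(d$part == p)
      idx <- idx[order(d$frame[idx])]
      x <- d$x[idx]; y <- d$y[idx]
      for (pass in seq_len(maxPasses)) {
        sp <- sqrt(diff(x)^2 + diff(y)^2)
        bad <- which(!is.na(sp) & sp > capPx) + 1L
        if (!length(bad)) break
        ## a single spike breaks two consecutive steps; remove only the first
        ## offending point of each run, then re-check
        bad <- bad[c(TRUE, diff(bad) > 1L)]
        x[bad] <- NA; y[bad] <- NA
        x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
        y <- zoo::na.approx(y, na.rm = FALSE, rule = 2)
        flags <- flags + length(bad)
      }
      d$x[idx] <- x; d$y[idx] <- y
    }
  }
  out <- new("Trajectory", data = d, fps = trajFps(traj),
             pxToMM = pxToMM(traj))
  attr(out, "speedFlags") <- flags
  out
}

#' @rdname applySpeedFilter
#' @param x a filtered \code{Trajectory}.
#' @export
speedFlags <- function(x) {
  f <- attr(x, "speedFlags")
  if (is.null(f)) 0L else f
}

#' Extract a time segment of a trajectory
#'
#' \code{extractSegment} keeps frames in [start, start + duration);
#' \code{centralSegment} centres the segment in the recording, the standard
#' choice for discarding acclimation at the start and disturbance at the end
#' (e.g. the central 2 minutes of a 5-minute video).
#'
#' @param traj a \code{Trajectory}.
#' @param start segment start, seconds from the first frame.
#' @param duration segment length, seconds.
#' @return The trimmed \code{Trajectory} (frames re-anchored at 0).
#' @export
extractSegment <- function(traj, start, duration) {
  stopifnot(is(traj, "Trajectory"))
  d <- trajData(traj)
  f0 <- min(d$frame)
  lo <- f0 + round(start * trajFps(traj))
  hi <- lo + round(duration * trajFps(traj))  # half-open
  d <- d[d$frame >= lo & d$frame < hi, , drop = FALSE]
  if (nrow(d) == 0) stop("segment outside recording", call. = FALSE)
  d$frame <- d$frame - lo
  new("Trajectory", data = d, fps = trajFps(traj), pxToMM = pxToMM(traj))
}

#' @rdname extractSegment
#' @export
centralSegment <- function(traj, duration = 120) {
  total <- nFrames(traj) / trajFps(traj)
  if (duration >= total) return(traj)
  extractSegment(traj, (total - duration) / 2, duration)
}

#' Extract one part as a frame-ordered coordinate matrix
#'
#' @param traj a \code{Trajectory}.
#' @param part part name.
#' @param dropNA drop frames with missing coordinates (default FALSE).
#' @return data.frame (frame, x, y, likelihood), frame-ordered.
#' @export
partSeries <- function(traj, part, dropNA = FALSE) {
  d <- trajData(traj)
  d <- d[d$part == part, c("frame", "x", "y", "likelihood"), drop = FALSE]
  if (nrow(d) == 0) stop("part not present: ", part, call. = FALSE)
  d <- d[order(d$frame), ]
  if (dropNA) d <- d[complete.cases(d[, c("x", "y")]), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a trajectory as a tidy CSV
#'
#' Long layout (frame, part, x, y, likelihood), compatible with common
#' pose-table formats.
#'
#' @param traj a \code{Trajectory}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path) {
  write.csv(trajData(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from a tidy CSV
#'
#' @param path CSV with columns frame, part, x, y and optionally likelihood.
#' @param fps acquisition rate, Hz.
#' @param pxToMM spatial calibration, mm/px.
#' @return A \code{Trajectory}.
#' @export
readTrajectory <- function(path, fps = 60, pxToMM = 0.055) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$likelihood)) d$likelihood <- 1
  new("Trajectory", data = d[, c("frame", "part", "x", "y", "likelihood")],
      fps = fps, pxToMM = pxToMM)
}
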