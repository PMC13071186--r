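## Arena geometry fitting and the behavioural feature set: kinematics, stop
## time, zone preference, wall interactions (thigmotaxis), body angles and
## turning, and the per-individual feature table.

collinearError <- function() {
  stop(structure(class = c("ethotox_collinear", "error", "condition"),
                 list(message = "points are collinear; no unique circle",
                      call = NULL)))
}

#' Fit the arena circle through three rim points
#'
#' Circumscribed circle (circumcentre and circumradius) of three pairwise
#' distinct, non-collinear points clicked on the dish rim.
#'
#' @param p1,p2,p3 numeric \code{(x, y)} px.
#' @param pxToMM spatial calibration for the resulting geometry (default
#'   0.055).
#' @param wallBandMM,innerFraction passed to \code{\link{arenaGeometry}}.
#' @param tol relative tolerance for the collinearity test.
#' @return An \code{ArenaGeometry}.
#' @examples
#' fitCircle(c(0, 0), c(2, 0), c(1, 1))
#' @export
fitCircle <- function(p1, p2, p3, pxToMM = 0.055, wallBandMM = 1,
                      innerFraction = 2 / 3, tol = 1e-12) {
  pts <- rbind(p1, p2, p3)
  if (any(duplicated(pts))) stop("points must be pairwise distinct",
                                 call. = FALSE)
  ## circumcentre from the perpendicular-bisector linear system
  ax <- pts[1, 1]; ay <- pts[1, 2]
  bx <- pts[2, 1]; by <- pts[2, 2]
  cx <- pts[3, 1]; cy <- pts[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale <- max(abs(pts)) + 1
  if (abs(d) < tol * scale^2) collinearError()
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  r <- unname(sqrt((ax - ux)^2 + (ay - uy)^2))
  arenaGeometry(centre = unname(c(ux, uy)), radius = r, pxToMM = pxToMM,
                wallBandMM = wallBandMM, innerFraction = innerFraction)
}

#' Kinematic summary of a conditioned trajectory
#'
#' Distance is the summed frame-to-frame displacement of the body centroid
#' (converted to mm); speeds are displacements times fps (mm/s);
#' acceleration is the frame-to-frame speed difference times fps (mm/s^2),
#' summarised as the mean absolute value; stop time is the number of frames
#' with speed below \code{stopSpeed}, divided by fps (s).
#'
#' @param traj a \code{Trajectory} (smoothed and speed-filtered upstream).
#' @param stopSpeed stop-bout threshold, mm/s (default 0.5).
#' @param part part to summarise (default \code{"body_centroid"}).
#' @return List: distance (mm), meanSpeed, maxSpeed (mm/s),
#'   meanAbsAcceleration (mm/s^2), stopTime (s), duration (s).
#' @export
kinematics <- function(traj, stopSpeed = 0.5, part = "body_centroid") {
  stopifnot(is(traj, "Trajectory"))
  s <- partSeries(traj, part, dropNA = TRUE)
  if (nrow(s) < 2) stop("need at least 2 frames", call. = FALSE)
  fps <- trajFps(traj)
  k <- pxToMM(traj)
  disp <- sqrt(diff(s$x)^2 + diff(s$y)^2) * k   # mm per frame
  speeds <- disp * fps                          # mm/s
  accel <- diff(speeds) * fps                   # mm/s^2
  ## per-frame speed series (first frame carries the first inter-frame speed)
  ## so a fully stationary recording is stopped for its whole duration
  frameSpeed <- c(speeds[1], speeds)
  list(distance = sum(disp),
       meanSpeed = mean(speeds),
       maxSpeed = max(speeds),
       meanAbsAcceleration = if (length(accel)) mean(abs(accel)) else 0,
       stopTime = sum(frameSpeed < stopSpeed) / fps,
       duration = nrow(s) / fps)
}

#' Time spent in the inner and outer arena zones
#'
#' Per-frame membership by distance to the arena centre against the inner
#' radius (a point exactly on the boundary counts as inner); the two times
#' sum to the analysed duration. Frames farther outside the circle than the
#' wall tolerance are clipped to the rim with a warning.
#'
#' @param traj a \code{Trajectory}.
#' @param arena an \code{ArenaGeometry}.
#' @param part part defining position (default body centroid).
#' @return List: innerTime, outerTime, duration (s).
#' @export
zoneTimes <- function(traj, arena, part = "body_centroid") {
  stopifnot(is(traj, "Trajectory"), is(arena, "ArenaGeometry"))
  s <- partSeries(traj, part, dropNA = TRUE)
  fps <- trajFps(traj)
  ctr <- arenaCentre(arena)
  rho <- sqrt((s$x - ctr[1])^2 + (s$y - ctr[2])^2)
  out <- rho > arenaRadius(arena) + wallBandPx(arena)
  if (any(out)) {
    warning(sum(out), " frame(s) outside the arena; clipped to the rim",
            call. = FALSE)
    rho[out] <- arenaRadius(arena)
  }
  inner <- rho <= innerRadius(arena)
  list(innerTime = sum(inner) / fps,
       outerTime = sum(!inner) / fps,
       duration = nrow(s) / fps)
}

#' Wall contacts of a body part (thigmotaxis)
#'
#' A frame is in contact when the part's distance to the arena centre is at
#' least radius minus the wall tolerance (1 mm band by default). Contact time
#' is the number of contact frames over fps. An event is an entry: a
#' transition from non-contact to contact, counted only when the contact run
#' lasts at least \code{minDwell} frames (debouncing single-frame jitter).
#' A trajectory that starts in contact counts one entry by convention.
#'
#' @param traj a \code{Trajectory}.
#' @param arena an \code{ArenaGeometry}.
#' @param part part name (an antenna tip for thigmotaxis counts; head or body
#'   centroid for wall-contact time).
#' @param minDwell minimum contact run length in frames (default 2).
#' @return List: contactTime (s), events (count), duration (s).
#' @export
wallInteractions <- function(traj, arena, part, minDwell = 2) {
  stopifnot(is(traj, "Trajectory"), is(arena, "ArenaGeometry"))
  s <- partSeries(traj, part, dropNA = TRUE)
  fps <- trajFps(traj)
  ctr <- arenaCentre(arena)
  rho <- sqrt((s$x - ctr[1])^2 + (s$y - ctr[2])^2)
  contact <- rho >= arenaRadius(arena) - wallBandPx(arena)
  r <- rle(contact)
  events <- sum(r$values & r$lengths >= minDwell)
  list(contactTime = sum(contact) / fps,
       events = events,
       duration = nrow(s) / fps)
}

#' Body axis angles
#'
#' Angle of the back-to-head segment with the x axis, computed with the
#' quadrant-resolved arctangent in arena coordinates: the image y axis points
#' down, so y is negated to make counter-clockwise positive ("left" turns are
#' counter-clockwise). Angles are normalized to [-pi, pi]. Frames with
#' coincident head and back carry the previous angle forward and are flagged
#' (attribute \code{"degenerate"}).
#'
#' @param head,back data.frames with x, y (paired rows, same frames).
#' @return Numeric vector of angles (rad), attribute \code{degenerate} =
#'   indices carried forward.
#' @export
bodyAngles <- function(head, back) {
  dx <- head$x - back$x
  dy <- -(head$y - back$y)   # image y down -> arena y up
  a <- atan2(dy, dx)
  degen <- which(dx == 0 & dy == 0)
  for (i in degen) a[i] <- if (i > 1) a[i - 1] else 0
  attr(a, "degenerate") <- degen
  a
}

wrapAngle <- function(d) {
  ## wrap to (-pi, pi]
  w <- ((d + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Turning behaviour from a body-angle series
#'
#' Frame-to-frame angle differences are wrapped to (-pi, pi]; positive
#' differences are counter-clockwise (left), negative clockwise (right).
#' Cumulative rotation is their running sum; the left (right) full-turn
#' counter increments each time the running sum crosses a new positive
#' (negative) multiple of 2*pi.
#'
#' @param angles numeric vector of body angles (rad).
#' @return List: leftTurns, rightTurns (counts), cumulativeRotation (rad,
#'   signed net), totalLeft, totalRight (rad accumulated per direction).
#' @export
turning <- function(angles) {
  if (length(angles) < 2) stop("need at least 2 angles", call. = FALSE)
  d <- wrapAngle(diff(angles))
  cum <- cumsum(d)
  ## small epsilon so an exact full turn is not lost to rounding
  leftTurns <- floor((max(c(0, cummax(cum))) + 1e-9) / (2 * pi))
  rightTurns <- floor((max(c(0, -cummin(cum))) + 1e-9) / (2 * pi))
  list(leftTurns = as.integer(leftTurns),
       rightTurns = as.integer(rightTurns),
       cumulativeRotation = sum(d),
       totalLeft = sum(d[d > 0]),
       totalRight = -sum(d[d < 0]))
}

#' Behavioural feature vector of one individual
#'
#' Applies the conditioning chain (rolling-mean smoothing, low-pass speed
#' filter) and computes the default feature set: distance, mean/max speed,
#' mean absolute acceleration, stop time, inner/outer zone times, wall
#' contact time (head), left/right antennal thigmotaxis entry counts, and
#' left/right turns with cumulative rotation.
#'
#' @param traj a raw \code{Trajectory} (with antenna parts if thigmotaxis
#'   sides are wanted).
#' @param arena an \code{ArenaGeometry}.
#' @param config a \code{\link{trackingConfig}}.
#' @return Named list of features (units: mm, mm/s, mm/s^2, s, counts, rad).
#' @export
extractFeatures <- function(traj, arena, config = trackingConfig()) {
  traj <- smoothTrajectory(traj, config$smoothWindow)
  traj <- applySpeedFilter(traj, config$speedCap)
  kin <- kinematics(traj, stopSpeed = config$stopSpeed)
  zt <- zoneTimes(traj, arena)
  parts <- unique(trajData(traj)$part)
  wallPart <- if ("head" %in% parts) "head" else "body_centroid"
  wc <- wallInteractions(traj, arena, wallPart)
  thL <- if ("antenna_L" %in% parts)
    wallInteractions(traj, arena, "antenna_L")$events else NA_integer_
  thR <- if ("antenna_R" %in% parts)
    wallInteractions(traj, arena, "antenna_R")$events else NA_integer_
  hd <- partSeries(traj, "head", dropNA = TRUE)
  bk <- partSeries(traj, "back", dropNA = TRUE)
  common <- intersect(hd$frame, bk$frame)
  ang <- bodyAngles(hd[hd$frame %in% common, ], bk[bk$frame %in% common, ])
  tn <- turning(ang)
  list(distance = kin$distance, meanSpeed = kin$meanSpeed,
       maxSpeed = kin$maxSpeed,
       meanAbsAcceleration = kin$meanAbsAcceleration,
       stopTime = kin$stopTime,
       innerTime = zt$innerTime, outerTime = zt$outerTime,
       wallContactTime = wc$contactTime,
       thigmoLeft = thL, thigmoRight = thR,
       leftTurns = tn$leftTurns, rightTurns = tn$rightTurns,
       cumulativeRotation = tn$cumulativeRotation,
       duration = kin$duration)
}

#' Feature names used for classification
#'
#' The default 10-feature classifier input: distance, mean and max speed,
#' mean absolute acceleration, stop time, inner and outer zone times, wall
#' contact time, and per-side antennal thigmotaxis counts.
#'
#' @return Character vector of 10 column names.
#' @export
classifierFeatures <- function() {
  c("distance", "meanSpeed", "maxSpeed", "meanAbsAcceleration", "stopTime",
    "innerTime", "outerTime", "wallContactTime", "thigmoLeft", "thigmoRight")
}

#' Feature table of a synthetic cohort
#'
#' One row per individual: the features of \code{\link{extractFeatures}} plus
#' group/sex/id labels. Trajectories come from the stored ground truth
#' (\code{\link{truthTrajectory}}); pass \code{segmentDuration} in
#' \code{config} shorter than the recording to analyse a central segment.
#'
#' @param cohort result of \code{\link{makeCohort}}.
#' @param config a \code{\link{trackingConfig}}.
#' @param arena optional override; defaults to each individual's own arena.
#' @return data.frame, one row per individual, with attribute \code{"units"}.
#' @export
buildFeatureTable <- function(cohort, config = trackingConfig(),
                              arena = NULL) {
  rows <- lapply(cohort$individuals, function(ind) {
    ar <- if (is.null(arena)) ind$truth@arena else arena
    traj <- truthTrajectory(ind$truth)
    cfg <- config
    cfg$fps <- trajFps(traj)
    cfg$pxToMM <- pxToMM(ar)
    fv <- extractFeatures(traj, ar, cfg)
    cbind(data.frame(id = ind$id, group = ind$group, sex = ind$sex,
                     stringsAsFactors = FALSE),
          as.data.frame(fv))
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  attr(tbl, "units") <- c(distance = "mm", meanSpeed = "mm/s",
                          maxSpeed = "mm/s", meanAbsAcceleration = "mm/s^2",
                          stopTime = "s", innerTime = "s", outerTime = "s",
                          wallContactTime = "s", thigmoLeft = "count",
                          thigmoRight = "count", leftTurns = "count",
                          rightTurns = "count", cumulativeRotation = "rad",
                          duration = "s")
  tbl
}

#' Write a feature table with a units sidecar
#'
#' CSV plus a JSON sidecar holding the units and the configuration used.
#'
#' @param tbl feature table from \code{\link{buildFeatureTable}}.
#' @param path CSV path; the sidecar gets extension .json.
#' @param config optional configuration list stored in the sidecar.
#' @return Invisibly, the CSV path.
#' @export
writeFeatureTable <- function(tbl, path, config = NULL) {
  write.csv(tbl, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(units = as.list(attr(tbl, "units")),
                            config = config),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
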