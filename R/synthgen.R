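## Synthetic arena generator: stop-and-go correlated random walk in a circular
## dish, rendered as a two-lobed dark body on a light background, with exact
## per-frame ground truth. Every downstream stage is validated against it.

#' Motion presets for the synthetic walker
#'
#' Constructs the parameter set of the stop-and-go correlated random walk.
#' Three named presets are built in: \code{"control"}, and the two treated
#' presets \code{"lc10"} and \code{"lc30"} which emulate sublethally exposed
#' individuals (progressively lower walking speed, go-state occupancy and
#' wall-following tendency than control). The preset ordering
#' control > lc10 > lc30 in configured mean speed and wall bias is asserted.
#'
#' @param label one of \code{"control"}, \code{"lc10"}, \code{"lc30"}, or any
#'   other label when all parameters are supplied explicitly.
#' @param meanSpeed mean walking speed while in the go state, mm/s.
#' @param speedDispersion between-individual lognormal sd of mean speed
#'   (unitless; used by \code{\link{makeCohort}}).
#' @param turnKappa concentration of the wrapped-normal heading increment;
#'   the per-frame turning sd is \code{1/sqrt(turnKappa)} rad.
#' @param stopRate per-frame probability of a go -> stop transition.
#' @param goRate per-frame probability of a stop -> go transition.
#' @param wallBias probability of steering tangentially (wall-following)
#'   rather than reflecting when inside the wall band.
#' @return A \code{MotionPreset} object.
#' @examples
#' motionPreset("control")
#' motionPreset("lc30")
#' @export
motionPreset <- function(label = c("control", "lc10", "lc30"),
                         meanSpeed = NULL, speedDispersion = NULL,
                         turnKappa = NULL, stopRate = NULL, goRate = NULL,
                         wallBias = NULL) {
  defaults <- list(
    control = list(meanSpeed = 6.0, speedDispersion = 0.45, turnKappa = 150,
                   stopRate = 0.02, goRate = 0.10, wallBias = 0.80),
    lc10    = list(meanSpeed = 4.2, speedDispersion = 0.45, turnKappa = 150,
                   stopRate = 0.05, goRate = 0.06, wallBias = 0.60),
    lc30    = list(meanSpeed = 3.0, speedDispersion = 0.45, turnKappa = 150,
                   stopRate = 0.08, goRate = 0.05, wallBias = 0.45)
  )
  label <- label[1]
  base <- defaults[[label]]
  if (is.null(base)) base <- defaults$control
  pick <- function(x, d) if (is.null(x)) d else x
  new("MotionPreset",
      label = label,
      meanSpeed = pick(meanSpeed, base$meanSpeed),
      speedDispersion = pick(speedDispersion, base$speedDispersion),
      turnKappa = pick(turnKappa, base$turnKappa),
      stopRate = pick(stopRate, base$stopRate),
      goRate = pick(goRate, base$goRate),
      wallBias = pick(wallBias, base$wallBias))
}

#' Circular arena geometry
#'
#' @param centre arena centre \code{(x, y)} in px (image convention: origin
#'   top-left, y down).
#' @param radius arena radius in px.
#' @param pxToMM spatial calibration, mm per pixel (default 0.055).
#' @param wallBandMM width of the wall-contact band, mm (default 1).
#' @param innerFraction inner-zone radius as a fraction of \code{radius}
#'   (default 2/3).
#' @return An \code{ArenaGeometry} object.
#' @examples
#' arenaGeometry(centre = c(960, 540), radius = 454)
#' @export
arenaGeometry <- function(centre, radius, pxToMM = 0.055, wallBandMM = 1,
                          innerFraction = 2 / 3) {
  new("ArenaGeometry", centre = as.numeric(centre), radius = radius,
      pxToMM = pxToMM, wallBandMM = wallBandMM, innerFraction = innerFraction)
}

## Body geometry (px), derived from body length. Two overlapping ellipses:
## a large back lobe and a small head lobe ahead of it along the heading, with
## a narrow waist at the junction so progressive erosion separates them. The
## antenna tips sit anterior of the head centroid at +/- 25 deg off-axis.
bodyGeometry <- function(bodyLengthPx) {
  L <- bodyLengthPx
  list(
    lengthPx = L,
    backAxes = c(0.30, 0.17) * L,   # semi-major (along axis), semi-minor
    headAxes = c(0.15, 0.12) * L,
    headOffset = 0.42 * L,          # back centroid -> head centroid; the
                                    # small ellipse overlap leaves a narrow
                                    # neck between the lobes
    antennaOffset = 0.25 * L,       # head centroid -> antenna tip
    antennaAngle = 25 * pi / 180,
    bodyGrey = 10,
    bgGrey = 110
  )
}

#' Simulate a ground-truth trajectory in a circular arena
#'
#' Stop-and-go correlated random walk confined to the dish. While in the go
#' state the walker takes gamma-distributed steps with mean
#' \code{meanSpeed / fps}; the heading evolves by wrapped-normal increments
#' with sd \code{1/sqrt(turnKappa)}. Inside the wall band the walker steers
#' tangentially with probability \code{wallBias} (wall-following /
#' thigmotaxis), otherwise its heading is reflected off the wall. The stop/go
#' state starts from the stationary distribution of its two-state chain.
#'
#' Coordinates follow the image convention (origin top-left, x right, y down);
#' the back centroid is the walker position, the head centroid sits
#' \code{headOffset} px ahead along the heading, and the two antenna tips sit
#' anterior of the head at +/- 25 degrees off-axis.
#'
#' @param preset a \code{\link{motionPreset}}.
#' @param nFrames number of frames (>= 2).
#' @param fps acquisition rate, Hz.
#' @param arena an \code{\link{arenaGeometry}}.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param bodyLengthMM body length used for the rendered silhouette and for
#'   keypoint offsets, mm (default 4).
#' @return A \code{GroundTruth} object.
#' @examples
#' ar <- arenaGeometry(centre = c(120, 120), radius = 110, pxToMM = 25 / 110)
#' gt <- simulateTrajectory(motionPreset("control"), nFrames = 100, fps = 60,
#'                          arena = ar, seed = 1)
#' gt
#' @export
simulateTrajectory <- function(preset, nFrames, fps, arena, seed = 1,
                               bodyLengthMM = 4) {
  stopifnot(is(preset, "MotionPreset"), is(arena, "ArenaGeometry"))
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (arenaRadius(arena) <= 0) stop("arena radius must be positive", call. = FALSE)
  if (nFrames < 2) stop("nFrames must be >= 2", call. = FALSE)
  L <- bodyLengthMM / pxToMM(arena)
  if (arenaRadius(arena) <= L)
    stop("arena radius must exceed body length", call. = FALSE)
  body <- bodyGeometry(L)

  set.seed(as.integer(seed))
  r <- arenaRadius(arena)
  ctr <- arenaCentre(arena)
  maxR <- r - 0.185 * L                # back centroid clamp: body half-width
                                       # (0.17 L) plus a small standoff
  bandR <- maxR - wallBandPx(arena)    # wall behaviour engages inside this band
  headLimit <- r - 0.10 * L            # hard limit for the head centroid

  stepMean <- preset@meanSpeed / fps / pxToMM(arena)  # px per frame
  turnSd <- 1 / sqrt(preset@turnKappa)

  ## stationary distribution of the stop/go chain
  pGo <- if (preset@stopRate + preset@goRate > 0)
    preset@goRate / (preset@stopRate + preset@goRate) else 1

  pos <- matrix(NA_real_, nFrames, 2)
  heading <- numeric(nFrames)
  moving <- logical(nFrames)

  rho0 <- sqrt(runif(1)) * 0.7 * maxR
  phi0 <- runif(1, 0, 2 * pi)
  pos[1, ] <- ctr + rho0 * c(cos(phi0), sin(phi0))
  heading[1] <- runif(1, -pi, pi)
  moving[1] <- runif(1) < pGo

  wrapPi <- function(a) atan2(sin(a), cos(a))

  nearTangent <- function(phi, th) {
    ## tangent direction (of the two) closest to the current heading
    t1 <- phi + pi / 2
    t2 <- phi - pi / 2
    if (cos(th - t1) >= cos(th - t2)) t1 else t2
  }

  ## angular rate limit: keypoints rigidly attached to the body axis must not
  ## swing faster than the low-pass speed cap used downstream
  maxTurn <- 0.22  # rad per frame
  rateLimit <- function(prev, desired) {
    d <- wrapPi(desired - prev)
    wrapPi(prev + max(-maxTurn, min(maxTurn, d)))
  }
  headOK <- function(p, th) {
    hx <- p + body$headOffset * c(cos(th), sin(th))
    sqrt(sum((hx - ctr)^2)) <= headLimit
  }

  for (i in 2:nFrames) {
    moving[i] <- if (moving[i - 1]) runif(1) >= preset@stopRate
                 else runif(1) < preset@goRate
    prevTh <- heading[i - 1]
    th <- prevTh
    p <- pos[i - 1, ]
    if (moving[i]) {
      th <- wrapPi(th + rnorm(1, 0, turnSd))
      rel <- p - ctr
      rho <- sqrt(sum(rel^2))
      if (rho > bandR) {
        ## inside the wall band: follow the wall or turn away
        phi <- atan2(rel[2], rel[1])
        if (runif(1) < preset@wallBias) {
          ## wall-following: tangent plus a small radial correction that
          ## regulates toward a hugging radius just inside the clamp
          tg <- nearTangent(phi, th)
          eps <- max(-0.25, min(0.25, 0.02 * ((maxR - 1) - rho)))
          sgn <- if (wrapPi(tg - phi) > 0) -1 else 1
          th <- wrapPi(tg + sgn * eps)
        } else {
          th <- wrapPi(2 * (phi + pi / 2) - th)  # reflect off the wall tangent
          if (cos(th - (phi + pi)) < 0)
            th <- wrapPi(phi + pi + runif(1, -1, 1))
        }
      }
      th <- rateLimit(prevTh, th)
    }
    step <- if (moving[i]) rgamma(1, shape = 4, rate = 4 / stepMean) else 0
    cand <- p + step * c(cos(th), sin(th))
    crel <- cand - ctr
    crho <- sqrt(sum(crel^2))
    if (crho > maxR) {
      ## reflect the heading off the wall tangent (rate-limited) and clamp
      phi <- atan2(crel[2], crel[1])
      th <- rateLimit(prevTh, wrapPi(2 * (phi + pi / 2) - th))
      cand <- ctr + crel / crho * maxR
    }
    ## the head cannot poke through the wall: brake and/or hold the previous
    ## heading so the head centroid never breaches its limit
    if (!headOK(cand, th)) {
      if (headOK(cand, prevTh)) {
        th <- prevTh
      } else if (headOK(p, th)) {
        cand <- p
      } else {
        cand <- p
        th <- prevTh
      }
    }
    pos[i, ] <- cand
    heading[i] <- th
  }

  hd <- pos + body$headOffset * cbind(cos(heading), sin(heading))
  aL <- hd + body$antennaOffset *
    cbind(cos(heading - body$antennaAngle), sin(heading - body$antennaAngle))
  aR <- hd + body$antennaOffset *
    cbind(cos(heading + body$antennaAngle), sin(heading + body$antennaAngle))

  truth <- data.frame(
    frame = seq_len(nFrames) - 1L,
    backX = pos[, 1], backY = pos[, 2],
    headX = hd[, 1], headY = hd[, 2],
    antLX = aL[, 1], antLY = aL[, 2],
    antRX = aR[, 1], antRY = aR[, 2],
    heading = heading, moving = moving
  )
  new("GroundTruth", truth = truth, arena = arena, fps = fps,
      preset = preset, body = body)
}

## Raster of one ellipse on the pixel grid [x0, x0+w) x [y0, y0+h) (0-based
## pixel centres at integer coordinates). Returns a logical matrix (h x w,
## row = y).
rasterEllipse <- function(centre, axes, angle, x0, y0, w, h) {
  xs <- x0 + seq_len(w) - 1
  ys <- y0 + seq_len(h) - 1
  dx <- matrix(xs, h, w, byrow = TRUE) - centre[1]
  dy <- matrix(ys, h, w) - centre[2]
  u <- cos(angle); v <- sin(angle)
  (( dx * u + dy * v) / axes[1])^2 + ((-dx * v + dy * u) / axes[2])^2 <= 1
}

#' Render one synthetic frame
#'
#' Draws the two-lobed body (small head ellipse + larger back ellipse, areas
#' strictly ordered by construction) as dark pixels on a light background and
#' adds Gaussian pixel noise. The exact silhouette and the per-lobe masks are
#' returned alongside the image, so segmentation and detection can be scored
#' against ground truth.
#'
#' @param gt a \code{GroundTruth} from \code{\link{simulateTrajectory}}.
#' @param frame frame index (0-based, matching \code{truthTable(gt)$frame}).
#' @param noiseSd sd of additive Gaussian noise, grey levels (default 5).
#' @param dims frame \code{c(width, height)} in px; default covers the arena.
#' @param body if \code{FALSE}, render only the background (no insect).
#' @return A list with \code{image} (numeric matrix, grey 0-255, row = y,
#'   column = x), \code{mask}, \code{headMask}, \code{backMask} (logical
#'   matrices), and \code{truthBoxes} (data.frame of half-open ground-truth
#'   bounding boxes for head and back).
#' @examples
#' ar <- arenaGeometry(centre = c(60, 60), radius = 55, pxToMM = 25 / 55)
#' gt <- simulateTrajectory(motionPreset("control"), 10, 60, ar, seed = 1)
#' fr <- renderFrame(gt, frame = 0, noiseSd = 0)
#' dim(fr$image)
#' @export
renderFrame <- function(gt, frame = 0, noiseSd = 5, dims = NULL, body = TRUE) {
  stopifnot(is(gt, "GroundTruth"))
  geom <- gt@body
  ar <- gt@arena
  if (is.null(dims)) {
    side <- ceiling(2 * arenaRadius(ar) + 8)
    dims <- c(side, side)
  }
  w <- dims[1]; h <- dims[2]
  img <- matrix(geom$bgGrey, h, w)
  mask <- matrix(FALSE, h, w)
  headMask <- mask
  backMask <- mask
  boxes <- NULL
  if (body) {
    tr <- gt@truth[gt@truth$frame == frame, , drop = FALSE]
    if (nrow(tr) != 1L) stop("frame not present in ground truth", call. = FALSE)
    th <- tr$heading
    backMask <- rasterEllipse(c(tr$backX, tr$backY), geom$backAxes, th, 0, 0, w, h)
    headMask <- rasterEllipse(c(tr$headX, tr$headY), geom$headAxes, th, 0, 0, w, h)
    mask <- backMask | headMask
    if (!any(mask)) stop("silhouette does not fit in the frame", call. = FALSE)
    img[mask] <- geom$bodyGrey
    boxes <- rbind(maskBBox(headMask, "head"), maskBBox(backMask, "back"))
  }
  if (noiseSd > 0) {
    img <- img + matrix(rnorm(w * h, 0, noiseSd), h, w)
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  list(image = img, mask = mask, headMask = headMask, backMask = backMask,
       truthBoxes = boxes)
}

## Half-open bbox (xmin, ymin, xmax, ymax) of a logical mask, 0-based.
maskBBox <- function(mask, part = NA_character_) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  x <- idx[, 2] - 1L; y <- idx[, 1] - 1L
  data.frame(part = part,
             xmin = min(x), ymin = min(y),
             xmax = max(x) + 1L, ymax = max(y) + 1L,
             cx = mean(x), cy = mean(y),
             area = nrow(idx), confidence = 1)
}

#' Ground-truth part detections for a set of frames
#'
#' Rasterizes the true head and back lobes of each requested frame and returns
#' their bounding boxes in the detection table layout used by
#' \code{\link{evaluateDetection}}.
#'
#' @inheritParams renderFrame
#' @param frames integer vector of frame indices.
#' @return A data.frame with columns frame, part, xmin, ymin, xmax, ymax,
#'   cx, cy, area, confidence.
#' @export
truthDetections <- function(gt, frames, dims = NULL) {
  out <- lapply(frames, function(f) {
    fr <- renderFrame(gt, f, noiseSd = 0, dims = dims)
    cbind(frame = f, fr$truthBoxes)
  })
  do.call(rbind, out)
}

#' Convert ground truth to a Trajectory
#'
#' Exposes the exact simulated keypoints in the long trajectory layout
#' (likelihood 1 everywhere), with the body centroid as the head/back
#' midpoint. This stands in for the video-tracking stage when the vision
#' pipeline is bypassed.
#'
#' @param gt a \code{GroundTruth}.
#' @return A \code{Trajectory}.
#' @export
truthTrajectory <- function(gt) {
  stopifnot(is(gt, "GroundTruth"))
  tr <- gt@truth
  long <- function(part, x, y)
    data.frame(frame = tr$frame, part = part, x = x, y = y, likelihood = 1)
  dat <- rbind(
    long("head", tr$headX, tr$headY),
    long("back", tr$backX, tr$backY),
    long("body_centroid", (tr$headX + tr$backX) / 2, (tr$headY + tr$backY) / 2),
    long("antenna_L", tr$antLX, tr$antLY),
    long("antenna_R", tr$antRX, tr$antRY)
  )
  new("Trajectory", data = dat, fps = gt@fps, pxToMM = pxToMM(gt@arena))
}

#' Generate a synthetic cohort
#'
#' One simulated individual per cell replicate of a groups x sexes x n design,
#' mirroring a behavioural assay in which equal numbers of males and females
#' are recorded per treatment group. Per-individual seeds and biological
#' variability (lognormal jitter of mean speed, logit-normal jitter of wall
#' bias, scale \code{speedDispersion}) are derived deterministically from the
#' master seed, so the whole cohort is reproducible.
#'
#' @param groups character vector of group labels; each must match a preset in
#'   \code{presets}.
#' @param sexes character vector of sex labels.
#' @param n individuals per group x sex cell.
#' @param nFrames frames per individual.
#' @param fps acquisition rate, Hz.
#' @param arena an \code{\link{arenaGeometry}}.
#' @param seed master seed.
#' @param presets named list of \code{\link{motionPreset}} objects; defaults to
#'   the built-in control/lc10/lc30 presets for the matching group labels.
#' @return A list with \code{individuals} (list of records: id, group, sex,
#'   seed, truth) and \code{design} (data.frame of labels); total size
#'   length(groups) * length(sexes) * n.
#' @examples
#' ar <- arenaGeometry(centre = c(120, 120), radius = 110, pxToMM = 25 / 110)
#' coh <- makeCohort(groups = "control", sexes = "F", n = 1, nFrames = 10,
#'                   fps = 60, arena = ar, seed = 7)
#' length(coh$individuals)
#' @export
makeCohort <- function(groups = c("control", "lc10", "lc30"),
                       sexes = c("M", "F"), n = 32, nFrames = 600, fps = 60,
                       arena, seed = 1, presets = NULL) {
  if (length(groups) < 1 || length(sexes) < 1 || n < 1)
    stop("empty cohort design", call. = FALSE)
  if (is.null(presets))
    presets <- setNames(lapply(groups, motionPreset), groups)
  design <- expand.grid(rep = seq_len(n), sex = sexes, group = groups,
                        stringsAsFactors = FALSE)[, c("group", "sex", "rep")]
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483L * 1000L, nrow(design))
  individuals <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    base <- presets[[design$group[i]]]
    set.seed(seeds[i])
    ms <- base@meanSpeed * rlnorm(1, 0, base@speedDispersion)
    wb <- stats::plogis(stats::qlogis(min(max(base@wallBias, 1e-6), 1 - 1e-6)) +
                        rnorm(1, 0, 0.3))
    indiv <- new("MotionPreset", label = base@label, meanSpeed = ms,
                 speedDispersion = base@speedDispersion,
                 turnKappa = base@turnKappa, stopRate = base@stopRate,
                 goRate = base@goRate, wallBias = wb)
    individuals[[i]] <- list(
      id = sprintf("%s_%s_%02d", design$group[i], design$sex[i], design$rep[i]),
      group = design$group[i], sex = design$sex[i], seed = seeds[i],
      truth = simulateTrajectory(indiv, nFrames, fps, arena, seed = seeds[i])
    )
  }
  list(individuals = individuals, design = design, seed = seed)
}

#' Write ground truth and arena descriptor to disk
#'
#' Ground truth is written as a long CSV (frame, part, x, y) and the arena as
#' a JSON descriptor, the interchange formats shared with the tracking stage.
#'
#' @param gt a \code{GroundTruth}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
writeGroundTruth <- function(gt, dir, prefix = "truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- trajData(truthTrajectory(gt))
  csv <- file.path(dir, paste0(prefix, "_keypoints.csv"))
  write.csv(traj[, c("frame", "part", "x", "y")], csv, row.names = FALSE)
  ar <- gt@arena
  js <- file.path(dir, paste0(prefix, "_arena.json"))
  jsonlite::write_json(
    list(centre = arenaCentre(ar), radius = arenaRadius(ar),
         px_to_mm = pxToMM(ar), wall_band_mm = ar@wallBandMM,
         inner_fraction = ar@innerFraction, fps = gt@fps),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(keypoints = csv, arena = js))
}

#' Write rendered frames as PNG files
#'
#' @param gt a \code{GroundTruth}.
#' @param frames frame indices to render.
#' @param dir output directory.
#' @param noiseSd rendering noise sd, grey levels.
#' @param dims optional frame dimensions \code{c(width, height)}.
#' @return Invisibly, the written file paths.
#' @export
writeFrames <- function(gt, frames, dir, noiseSd = 5, dims = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(frames, function(f) {
    fr <- renderFrame(gt, f, noiseSd = noiseSd, dims = dims)
    p <- file.path(dir, sprintf("frame_%05d.png", f))
    EBImage::writeImage(t(fr$image) / 255, p)
    p
  }, character(1))
  invisible(paths)
}
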