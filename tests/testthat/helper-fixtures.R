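## Shared fixtures. Rendering tests use the native 0.055 mm/px calibration in
## a compact 12 mm dish so the insect has its real pixel size while frames
## stay small; feature tests use the full 25 mm dish without rendering.

smallDish <- function() {
  arenaGeometry(centre = c(222, 222), radius = 218, pxToMM = 0.055)
}

bigDish <- function() {
  arenaGeometry(centre = c(460, 460), radius = 454, pxToMM = 0.055)
}

## cohort shared by the feature/classification tests (built once per run)
.fixtureCache <- new.env(parent = emptyenv())

cachedCohort <- function() {
  if (is.null(.fixtureCache$cohort)) {
    .fixtureCache$cohort <- makeCohort(
      groups = c("control", "lc10", "lc30"), sexes = c("M", "F"), n = 16,
      nFrames = 2400, fps = 60, arena = bigDish(), seed = 11)
  }
  .fixtureCache$cohort
}

cachedFeatureTable <- function() {
  if (is.null(.fixtureCache$features)) {
    .fixtureCache$features <- buildFeatureTable(cachedCohort())
  }
  .fixtureCache$features
}

## build a Trajectory from scripted coordinates (single part)
scriptTrajectory <- function(x, y, fps = 60, pxToMM = 0.055,
                             part = "body_centroid") {
  new("Trajectory",
      data = data.frame(frame = seq_along(x) - 1L, part = part, x = x, y = y,
                        likelihood = 1),
      fps = fps, pxToMM = pxToMM)
}

## filled disc mask on an h x w grid (row = y), 1-based centre
discMask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}
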