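#' @import methods
#' @importFrom stats approx coef complete.cases glm optim pchisq pnorm qnorm
#'   rbinom rgamma rlnorm rnorm runif sd setNames var vcov binomial kruskal.test
#'   shapiro.test p.adjust predict quantile median
#' @importFrom utils head tail modifyList write.csv read.csv packageVersion
NULL

## ---------------------------------------------------------------------------
## MotionPreset: parameters of the stop-and-go correlated random walk used by
## the synthetic generator. Speeds are in mm/s; rates are per-frame transition
## probabilities of the two-state stop/go process; turnKappa is the
## concentration of the wrapped-normal heading increment (larger = straighter);
## wallBias is the probability of steering tangentially while in the wall band.
## ---------------------------------------------------------------------------

#' @rdname motionPreset
#' @export
setClass("MotionPreset",
  slots = c(
    label = "character",
    meanSpeed = "numeric",
    speedDispersion = "numeric",
    turnKappa = "numeric",
    stopRate = "numeric",
    goRate = "numeric",
    wallBias = "numeric"
  )
)

setValidity("MotionPreset", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  if (object@meanSpeed <= 0) msg <- c(msg, "meanSpeed must be > 0")
  if (object@speedDispersion < 0) msg <- c(msg, "speedDispersion must be >= 0")
  if (object@turnKappa <= 0) msg <- c(msg, "turnKappa must be > 0")
  rates <- c(stopRate = object@stopRate, goRate = object@goRate,
             wallBias = object@wallBias)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    msg <- c(msg, paste(names(rates)[bad], "must lie in [0, 1]"))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ArenaGeometry: the circular dish in pixel coordinates (image convention:
## origin top-left, x right, y down) plus the px -> mm conversion. The inner
## zone has radius innerFraction * radius; the wall band is wallBandMM wide.
## ---------------------------------------------------------------------------

#' @rdname arenaGeometry
#' @export
setClass("ArenaGeometry",
  slots = c(
    centre = "numeric",
    radius = "numeric",
    pxToMM = "numeric",
    wallBandMM = "numeric",
    innerFraction = "numeric"
  )
)

setValidity("ArenaGeometry", function(object) {
  msg <- character()
  if (length(object@centre) != 2L) msg <- c(msg, "centre must be (x, y)")
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@pxToMM <= 0) msg <- c(msg, "pxToMM must be > 0")
  if (object@wallBandMM < 0) msg <- c(msg, "wallBandMM must be >= 0")
  if (object@innerFraction <= 0 || object@innerFraction >= 1)
    msg <- c(msg, "innerFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GroundTruth: per-frame true keypoints of one simulated individual, plus the
## arena, the preset that generated it, and the body geometry used by the
## renderer (all lengths in px).
## ---------------------------------------------------------------------------

#' @rdname simulateTrajectory
#' @export
setClass("GroundTruth",
  slots = c(
    truth = "data.frame",
    arena = "ArenaGeometry",
    fps = "numeric",
    preset = "MotionPreset",
    body = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  need <- c("frame", "headX", "headY", "backX", "backY",
            "antLX", "antLY", "antRX", "antRY", "heading", "moving")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, paste("truth must have columns:", paste(need, collapse = ", ")))
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Trajectory: long-format keypoint time series (frame, part, x, y, likelihood)
## with acquisition rate and spatial calibration.
## ---------------------------------------------------------------------------

#' @rdname trajectory
#' @export
setClass("Trajectory",
  slots = c(
    data = "data.frame",
    fps = "numeric",
    pxToMM = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  need <- c("frame", "part", "x", "y", "likelihood")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data must have columns:", paste(need, collapse = ", ")))
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (object@pxToMM <= 0) msg <- c(msg, "pxToMM must be > 0")
  lk <- object@data$likelihood
  if (length(lk) && any(!is.na(lk) & (lk < 0 | lk > 1)))
    msg <- c(msg, "likelihood must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ProbitFit: binomial-probit concentration-mortality model on log10 dose,
## probit(p) = a + b * log10(dose).
## ---------------------------------------------------------------------------

#' @rdname fitProbit
#' @export
setClass("ProbitFit",
  slots = c(
    coef = "numeric",           # c(a = intercept, b = slope)
    vcov = "matrix",
    chisq = "numeric",
    df = "numeric",
    data = "data.frame",
    controlMortality = "numeric"
  )
)

setValidity("ProbitFit", function(object) {
  msg <- character()
  if (length(object@coef) != 2L) msg <- c(msg, "coef must be c(a, b)")
  if (!all(dim(object@vcov) == c(2L, 2L))) msg <- c(msg, "vcov must be 2x2")
  if (length(msg)) msg else TRUE
})
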