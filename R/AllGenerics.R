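## Accessor generics. Slot access from user code is discouraged; these are the
## supported surface.

#' Accessors for ethotox S4 classes
#'
#' Small family of accessors for the core containers: arena geometry
#' (\code{arenaCentre}, \code{arenaRadius}, \code{innerRadius},
#' \code{wallBandPx}, \code{pxToMM}), trajectories (\code{trajData},
#' \code{trajFps}, \code{nFrames}), ground truth (\code{truthTable},
#' \code{arena}), and probit fits (\code{probitCoef}, \code{probitVcov}).
#'
#' @param object an ethotox S4 object.
#' @return The corresponding component; see each method.
#' @examples
#' ar <- arenaGeometry(centre = c(100, 100), radius = 90, pxToMM = 0.28)
#' arenaRadius(ar)
#' innerRadius(ar)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("arenaCentre", function(object) standardGeneric("arenaCentre"))
#' @rdname accessors
#' @export
setGeneric("arenaRadius", function(object) standardGeneric("arenaRadius"))
#' @rdname accessors
#' @export
setGeneric("innerRadius", function(object) standardGeneric("innerRadius"))
#' @rdname accessors
#' @export
setGeneric("wallBandPx", function(object) standardGeneric("wallBandPx"))
#' @rdname accessors
#' @export
setGeneric("pxToMM", function(object) standardGeneric("pxToMM"))
#' @rdname accessors
#' @export
setGeneric("trajData", function(object) standardGeneric("trajData"))
#' @rdname accessors
#' @export
setGeneric("trajFps", function(object) standardGeneric("trajFps"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("arena", function(object) standardGeneric("arena"))
#' @rdname accessors
#' @export
setGeneric("probitCoef", function(object) standardGeneric("probitCoef"))
#' @rdname accessors
#' @export
setGeneric("probitVcov", function(object) standardGeneric("probitVcov"))

#' @rdname accessors
#' @export
setMethod("arenaCentre", "ArenaGeometry", function(object) object@centre)
#' @rdname accessors
#' @export
setMethod("arenaRadius", "ArenaGeometry", function(object) object@radius)
#' @rdname accessors
#' @export
setMethod("innerRadius", "ArenaGeometry",
          function(object) object@innerFraction * object@radius)
#' @rdname accessors
#' @export
setMethod("wallBandPx", "ArenaGeometry",
          function(object) object@wallBandMM / object@pxToMM)
#' @rdname accessors
#' @export
setMethod("pxToMM", "ArenaGeometry", function(object) object@pxToMM)
#' @rdname accessors
#' @export
setMethod("pxToMM", "Trajectory", function(object) object@pxToMM)
#' @rdname accessors
#' @export
setMethod("trajData", "Trajectory", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("trajFps", "Trajectory", function(object) object@fps)
#' @rdname accessors
#' @export
setMethod("trajFps", "GroundTruth", function(object) object@fps)
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory",
          function(object) length(unique(object@data$frame)))
#' @rdname accessors
#' @export
setMethod("nFrames", "GroundTruth", function(object) nrow(object@truth))
#' @rdname accessors
#' @export
setMethod("truthTable", "GroundTruth", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("arena", "GroundTruth", function(object) object@arena)
#' @rdname accessors
#' @export
setMethod("probitCoef", "ProbitFit", function(object) object@coef)
#' @rdname accessors
#' @export
setMethod("probitVcov", "ProbitFit", function(object) object@vcov)

## show methods -------------------------------------------------------------

setMethod("show", "MotionPreset", function(object) {
  cat(sprintf(
    "MotionPreset '%s': meanSpeed %.2f mm/s (dispersion %.2f), turnKappa %.1f\n",
    object@label, object@meanSpeed, object@speedDispersion, object@turnKappa))
  cat(sprintf("  stop/go rates %.3f/%.3f, wallBias %.2f\n",
              object@stopRate, object@goRate, object@wallBias))
})

setMethod("show", "ArenaGeometry", function(object) {
  cat(sprintf(
    "ArenaGeometry: centre (%.1f, %.1f) px, radius %.1f px (%.1f mm)\n",
    object@centre[1], object@centre[2], object@radius,
    object@radius * object@pxToMM))
  cat(sprintf("  inner zone radius %.1f px (fraction %.3f), wall band %.2f mm = %.1f px\n",
              innerRadius(object), object@innerFraction, object@wallBandMM,
              wallBandPx(object)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames at %g fps, preset '%s'\n",
              nrow(object@truth), object@fps, object@preset@label))
  show(object@arena)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames at %g fps, %d part(s), %.3f mm/px\n",
              nFrames(object), object@fps,
              length(unique(object@data$part)), object@pxToMM))
})

setMethod("show", "ProbitFit", function(object) {
  cat(sprintf("ProbitFit: probit(p) = %.4f + %.4f * log10(dose)\n",
              object@coef[1], object@coef[2]))
  if (is.finite(object@chisq))
    cat(sprintf("  Pearson chi-square %.2f on %d df\n",
                object@chisq, as.integer(object@df)))
  if (object@controlMortality > 0)
    cat(sprintf("  Abbott control mortality %.3f\n", object@controlMortality))
})
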