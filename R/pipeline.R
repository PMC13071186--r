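## Orchestration: one configuration object with the canonical defaults, a
## YAML round-trip, and a staged runner writing artifacts plus a manifest.

#' Pipeline configuration
#'
#' Single nested configuration covering all stages, with defaults matching
#' the canonical assay parameters: binarization threshold 60, 5x5 Gaussian
#' blur, at most 10 erosions, 3-frame smoothing window, 0.055 mm/px, 1 mm
#' wall band, inner-zone fraction 2/3, 60 fps, central 2-minute analysis
#' segment. All randomness flows from the single master \code{seed}.
#'
#' @param ... overrides of the defaults, as nested lists (see the structure
#'   of the return value).
#' @return A list of class \code{"pipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(synth = list(n = 2), seed = 7)
#' cfg$tracking$fps
#' @export
pipelineConfig <- function(...) {
  base <- list(
    seed = 1,
    stages = list(synth = TRUE, autolabel = FALSE, features = TRUE,
                  stats = TRUE, classify = TRUE),
    synth = list(groups = c("control", "lc10", "lc30"), sexes = c("M", "F"),
                 n = 4, nFrames = 1200, arenaRadiusMM = 25,
                 arenaScale = 0.25, bodyLengthMM = 4),
    autolabel = list(blurKernel = 5, threshold = 60, maxIters = 10,
                     minArea = 5, iouThreshold = 0.5, noiseSd = 5,
                     nFrames = 40, ratios = c(0.70, 0.20, 0.10)),
    tracking = list(fps = 60, pxToMM = 0.055, smoothWindow = 3,
                    speedCap = 50, stopSpeed = 0.5, maxGap = 5,
                    segmentDuration = 120),
    arena = list(wallBandMM = 1, innerFraction = 2 / 3),
    classify = list(models = c("svm", "rf", "knn"),
                    pairs = list(c("control", "lc30"), c("control", "lc10"),
                                 c("lc10", "lc30")),
                    shapley = TRUE, backgroundCap = 64)
  )
  cfg <- modifyList(base, list(...))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip is lossless for all default fields.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param path YAML file path.
#' @return \code{writePipelineConfig}: invisibly, \code{path};
#'   \code{readPipelineConfig}: the configuration.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) cfg <- list()  # empty file -> all defaults
  do.call(pipelineConfig, cfg)
}

## tiny djb2-style rolling hash over the serialized object; enough to
## fingerprint a configuration in the manifest
configHash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' Executes the toggled stages in order — synthetic cohort generation,
#' automatic labelling + dataset export on sample frames, feature
#' extraction, group statistics, classification — writing per-stage
#' artifacts and a JSON manifest (package version, seed, configuration hash,
#' stage status) into \code{outDir}. Any stage failure aborts with a
#' stage-named error after writing a partial manifest.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the stage results and the manifest path.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir, quiet = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ethotox",
                   version = as.character(packageVersion("ethotox")),
                   r_version = as.character(getRversion()),
                   seed = cfg$seed, config_hash = configHash(unclass(cfg)),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  manifestPath <- file.path(outDir, "manifest.json")
  say <- function(...) if (!quiet) message(...)
  fail <- function(stage, e) {
    manifest$stages[[stage]] <- list(status = "failed",
                                     error = conditionMessage(e))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  results <- list()

  ## stage: synth ------------------------------------------------------------
  if (!isTRUE(cfg$stages$synth))
    stop("configuration error: no input stage enabled (synth is off and no ",
         "external input is configured)", call. = FALSE)
  results$cohort <- tryCatch({
    s <- cfg$synth
    pxmm <- cfg$tracking$pxToMM / s$arenaScale
    radius <- s$arenaRadiusMM / pxmm
    ar <- arenaGeometry(centre = c(radius + 4, radius + 4), radius = radius,
                        pxToMM = pxmm, wallBandMM = cfg$arena$wallBandMM,
                        innerFraction = cfg$arena$innerFraction)
    coh <- makeCohort(groups = s$groups, sexes = s$sexes, n = s$n,
                      nFrames = s$nFrames, fps = cfg$tracking$fps,
                      arena = ar, seed = cfg$seed)
    say("synth: ", length(coh$individuals), " individuals")
    manifest$stages$synth <- list(status = "ok",
                                   individuals = length(coh$individuals))
    coh
  }, error = function(e) fail("synth", e))

  ## stage: autolabel ---------------------------------------------------------
  if (isTRUE(cfg$stages$autolabel)) {
    results$autolabel <- tryCatch({
      al <- cfg$autolabel
      gt <- results$cohort$individuals[[1]]$truth
      n <- min(al$nFrames, nFrames(gt))
      set.seed(cfg$seed)
      det <- labelFrames(function(i)
        renderFrame(gt, i - 1L, noiseSd = al$noiseSd)$image, n = n,
        blurKernel = al$blurKernel, threshold = al$threshold,
        maxIters = al$maxIters, minArea = al$minArea)
      truth <- truthDetections(gt, 0:(n - 1L))
      mets <- evaluateDetection(det, truth, iouThreshold = al$iouThreshold)
      side <- ceiling(2 * arenaRadius(arena(gt)) + 8)
      ds <- exportDataset(det, file.path(outDir, "dataset"),
                          imageSize = c(side, side), ratios = al$ratios,
                          seed = cfg$seed)
      write.csv(mets$perClass, file.path(outDir, "detection_metrics.csv"),
                row.names = FALSE)
      say(sprintf("autolabel: %d frames, macro F1 %.3f", n, mets$overall$f1))
      manifest$stages$autolabel <- list(status = "ok", frames = n,
                                         splits = as.list(ds$counts),
                                         f1 = mets$overall$f1)
      list(metrics = mets, splits = ds$counts)
    }, error = function(e) fail("autolabel", e))
  }

  ## stage: features ----------------------------------------------------------
  if (isTRUE(cfg$stages$features)) {
    results$features <- tryCatch({
      tcfg <- do.call(trackingConfig,
                      cfg$tracking[c("fps", "pxToMM", "smoothWindow",
                                     "speedCap", "stopSpeed", "maxGap")])
      tbl <- buildFeatureTable(results$cohort, tcfg)
      writeFeatureTable(tbl, file.path(outDir, "features.csv"),
                        config = cfg$tracking)
      say("features: ", nrow(tbl), " rows")
      manifest$stages$features <- list(status = "ok", rows = nrow(tbl))
      tbl
    }, error = function(e) fail("features", e))
  }

  ## stage: stats -------------------------------------------------------------
  if (isTRUE(cfg$stages$stats) && !is.null(results$features)) {
    results$stats <- tryCatch({
      st <- compareFeatures(results$features)
      write.csv(st, file.path(outDir, "group_stats.csv"), row.names = FALSE)
      say("stats: ", nrow(st), " test rows")
      manifest$stages$stats <- list(status = "ok", tests = nrow(st))
      st
    }, error = function(e) fail("stats", e))
  }

  ## stage: classify ----------------------------------------------------------
  if (isTRUE(cfg$stages$classify) && !is.null(results$features)) {
    results$classify <- tryCatch({
      cl <- cfg$classify
      out <- lapply(cl$pairs, function(pr)
        compareGroups(results$features, pr, models = cl$models,
                      seed = cfg$seed, shapley = isTRUE(cl$shapley),
                      backgroundCap = cl$backgroundCap))
      names(out) <- vapply(cl$pairs, paste, character(1), collapse = "-")
      summ <- data.frame(pair = names(out),
                         meanAccuracy = vapply(out, `[[`, numeric(1),
                                               "meanAccuracy"),
                         meanPrecision = vapply(out, `[[`, numeric(1),
                                                "meanPrecision"))
      jsonlite::write_json(summ, file.path(outDir, "classification.json"),
                           digits = NA)
      for (nm in names(out)) {
        if (!is.null(out[[nm]]$shap))
          write.csv(out[[nm]]$shap,
                    file.path(outDir, paste0("shap_", nm, ".csv")),
                    row.names = FALSE)
        for (m in names(out[[nm]]$results))
          write.csv(out[[nm]]$results[[m]]$confusion,
                    file.path(outDir,
                              paste0("confusion_", nm, "_", m, ".csv")))
      }
      say("classify: ", paste(sprintf("%s %.2f", summ$pair,
                                      summ$meanAccuracy), collapse = ", "))
      manifest$stages$classify <- list(status = "ok",
                                        pairs = as.list(summ$meanAccuracy))
      out
    }, error = function(e) fail("classify", e))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  say("manifest: ", manifestPath)
  invisible(c(results, list(manifest = manifestPath)))
}
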