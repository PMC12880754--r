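#' Derive a stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed, split per
#' stage by a deterministic counter-based hash and logged in the manifest.
#'
#' @param rootSeed integer root seed.
#' @param stage stage label.
#' @return a derived integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(rootSeed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(rootSeed) * 7919 + h * 104729) %%
               (.Machine$integer.max - 1) + 1)
}

#' Run one hierarchical segmentation cycle
#'
#' Executes the stages of one resolution level in order: (optional)
#' preprocessing, training or fine-tuning, sliding-window inference over
#' the level's volume of interest, instance post-filtering, registration
#' into the next (lower-resolution) level, and pseudo-label generation for
#' it. The first level requires manual labels; later levels require the
#' previous model and the pseudo-labelled cubes produced upstream.
#'
#' @param level list describing the level: \code{levelId},
#'   \code{resolutionLevel} ("high"/"intermediate"/"low"), \code{image}
#'   (full-VOI \linkS4class{Volume3D}), \code{cubes} (list of
#'   \linkS4class{AnnotatedCube}; manual at the first level, pseudo
#'   afterwards), optional \code{truth} (binary \linkS4class{LabelVolume}
#'   for threshold search), optional \code{cortexMask}, and optional
#'   \code{nextLevel} = list(image, fixedPointUm, movingPointUm,
#'   resolutionLevel).
#' @param model previous-level backbone, or NULL at the first level.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param lossCfg a \code{\link{lossConfig}}.
#' @param thresholds a \linkS4class{ThresholdSet}, or "search" to run
#'   \code{\link{lhsSearch}} against \code{level$truth}, or NULL for the
#'   radius-floor default.
#' @param preprocessFun optional function Volume3D -> Volume3D applied to
#'   the level image and every cube image before training/inference.
#' @param valFraction fraction of cubes held out for EMA validation
#'   tracking (at least one cube).
#' @param overlapFraction sliding-window overlap.
#' @param splitTouching re-separate merged quasi-spherical instances with
#'   \code{\link{splitTouchingInstances}} before property computation.
#' @param rootSeed root seed; stage seeds are derived from it.
#' @return a CycleManifest: list with \code{manifest} (plain-data summary
#'   of every stage, JSON-serialisable), \code{model}, \code{probability}
#'   (\linkS4class{Volume3D}), \code{instances} (filtered instance
#'   \linkS4class{LabelVolume}), \code{thresholds}, \code{transform} (or
#'   NULL), \code{pseudoCubes} (filtered, or NULL) and \code{history}.
#' @export
runCycle <- function(level, model = NULL, trainCfg = trainConfig(),
                     lossCfg = lossConfig(), thresholds = NULL,
                     preprocessFun = NULL, valFraction = 0.2,
                     overlapFraction = 0.5, splitTouching = TRUE,
                     rootSeed = 1L) {
  if (is.null(model) && is.null(level$cubes))
    stop("manual labels required at the first level (stage: training data)")
  if (!is.null(model) && is.null(level$cubes))
    stop("missing pseudo-labelled cubes for fine-tuning (stage: training data)")
  if (is.null(level$image))
    stop("missing level image (stage: inference)")

  cubes <- level$cubes
  image <- level$image
  if (!is.null(preprocessFun)) {
    image <- preprocessFun(image)
    cubes <- lapply(cubes, function(cb) {
      cb@image <- preprocessFun(cb@image)
      cb
    })
  }

  # hold out cubes for EMA validation tracking
  seedSplit <- deriveSeed(rootSeed, paste0("split-", level$levelId))
  set.seed(seedSplit)
  nVal <- max(1L, floor(valFraction * length(cubes)))
  valIdx <- if (length(cubes) > 1) sample(seq_along(cubes), nVal)
            else integer(0)
  trainCubes <- cubes[setdiff(seq_along(cubes), valIdx)]
  valCubes <- cubes[valIdx]

  seedTrain <- deriveSeed(rootSeed, paste0("train-", level$levelId))
  trainPatches <- unlist(lapply(trainCubes, extractPatches,
                                patchEdge = trainCfg$patchEdge),
                         recursive = FALSE)
  valPatches <- if (length(valCubes))
    unlist(lapply(valCubes, extractPatches, patchEdge = trainCfg$patchEdge),
           recursive = FALSE) else NULL
  startModel <- if (is.null(model)) referenceBackbone() else model
  fit <- trainBackbone(startModel, trainPatches, valPatches,
                       epochs = trainCfg$epochs, lr = trainCfg$lr,
                       lossCfg = lossCfg, seed = seedTrain)

  prob <- slidingWindowInfer(fit$model, image,
                             window = trainCfg$patchEdge,
                             overlapFraction = overlapFraction)
  binary <- labelVolume(array(as.integer(voxels(prob) >= 0.5),
                              dim(voxels(prob))),
                        spacingUm = spacingUm(image),
                        originUm = originUm(image), kind = "binary")
  instances <- labelInstances(binary)
  if (splitTouching)
    instances <- splitTouchingInstances(instances)
  props <- computeProperties(instances, image,
                             cortexMask = level$cortexMask)

  seedLhs <- deriveSeed(rootSeed, paste0("lhs-", level$levelId))
  if (identical(thresholds, "search")) {
    if (is.null(level$truth))
      stop("threshold search requires level$truth (stage: post-filtering)")
    search <- lhsSearch(list(list(prediction = binary, truth = level$truth,
                                  image = image,
                                  cortexMask = level$cortexMask)),
                        seed = seedLhs)
    th <- search$bestThresholds
  } else if (is(thresholds, "ThresholdSet")) {
    th <- thresholds
  } else {
    th <- thresholdSet()
  }
  filtered <- applyThresholdSet(instances, props, th,
                                cortexMask = level$cortexMask)

  transform <- NULL
  pseudoCubes <- NULL
  nPseudoRaw <- NA_integer_
  if (!is.null(level$nextLevel)) {
    reg <- registerVolumes(level$nextLevel$image, image,
                           level$nextLevel$fixedPointUm,
                           level$nextLevel$movingPointUm)
    transform <- reg$transform
    resampled <- resampleLabels(filtered, transform, level$nextLevel$image)
    raw <- makePseudoCubes(level$nextLevel$image, resampled,
                           cubeEdge = trainCfg$patchEdge,
                           resolutionLevel = level$nextLevel$resolutionLevel)
    nPseudoRaw <- length(raw)
    seedKeep <- deriveSeed(rootSeed, paste0("cubes-", level$levelId))
    pseudoCubes <- filterTrainingCubes(raw,
                                       level = level$nextLevel$resolutionLevel,
                                       seed = seedKeep)
  }

  manifest <- list(
    levelId = level$levelId,
    resolutionLevel = level$resolutionLevel,
    mode = if (is.null(model)) "scratch" else "finetune",
    seeds = list(split = seedSplit, train = seedTrain, lhs = seedLhs,
                 root = rootSeed),
    nCubes = length(cubes), nTrainPatches = length(trainPatches),
    nValPatches = length(valPatches),
    epochs = trainCfg$epochs, patchEdge = trainCfg$patchEdge,
    finalTrainLoss = utils::tail(fit$history$trainLoss, 1),
    bestEmaValDice = if (length(valPatches))
      max(fit$history$valDiceEma, na.rm = TRUE) else NA_real_,
    thresholds = list(varianceLower = th@varianceLower,
                      varianceUpper = th@varianceUpper,
                      roundnessMin = th@roundnessMin,
                      radiusMinUm = th@radiusMinUm,
                      densityWindowW = th@densityWindowW,
                      densityMinCount = th@densityMinCount,
                      useCortexMask = th@useCortexMask),
    nInstancesRaw = max(labelArray(instances)),
    nInstancesKept = length(unique(
      labelArray(filtered)[labelArray(filtered) > 0])),
    transform = if (is.null(transform)) NULL else list(
      thetaZDeg = transform@thetaZDeg, thetaXYDeg = transform@thetaXYDeg,
      scale = transform@scale),
    nPseudoCubesRaw = nPseudoRaw,
    nPseudoCubesKept = if (is.null(pseudoCubes)) NA_integer_
                       else length(pseudoCubes))

  list(manifest = manifest, model = fit$model, probability = prob,
       instances = filtered, thresholds = th, transform = transform,
       pseudoCubes = pseudoCubes, history = fit$history)
}

#' Run the full hierarchical pipeline over a resolution chain
#'
#' Chains \code{\link{runCycle}} over strictly lower-resolution levels,
#' passing each cycle's model and pseudo-labelled cubes to the next.
#'
#' @param levels list of level configs (see \code{\link{runCycle}}); each
#'   level before the last must carry a \code{nextLevel} entry pointing at
#'   the following level's grid and common points.
#' @param trainCfg,lossCfg,thresholds,preprocessFun,rootSeed
#'   passed to each cycle.
#' @return list of cycle results, one per level.
#' @export
runPipeline <- function(levels, trainCfg = trainConfig(),
                        lossCfg = lossConfig(), thresholds = NULL,
                        preprocessFun = NULL, rootSeed = 1L) {
  out <- vector("list", length(levels))
  model <- NULL
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    if (i > 1 && is.null(lv$cubes))
      lv$cubes <- out[[i - 1]]$pseudoCubes
    out[[i]] <- runCycle(lv, model = model, trainCfg = trainCfg,
                         lossCfg = lossCfg, thresholds = thresholds,
                         preprocessFun = preprocessFun, rootSeed = rootSeed)
    model <- out[[i]]$model
  }
  out
}

#' Write a cycle manifest to JSON
#'
#' @param cycle a result from \code{\link{runCycle}}.
#' @param path JSON file path.
#' @export
writeManifest <- function(cycle, path) {
  jsonlite::write_json(cycle$manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
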