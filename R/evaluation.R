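#' Registration recovery suite on phantom pairs
#'
#' Generates a phantom, derives lower-resolution copies under random known
#' rigid+scale transforms (z-rotation uniform on [0, 360), scale uniform on
#' [0.95, 1.05]), registers the parent back onto each child with the full
#' staged search, and reports the absolute rotation and relative scale
#' recovery errors.
#'
#' @param nCases number of random transforms (default 10).
#' @param seed integer seed for the transform draws and the phantom.
#' @param volumeShape,spacingUm phantom geometry (parent level).
#' @return data.frame with columns thetaTrueDeg, scaleTrue, thetaErrDeg,
#'   scaleRelErr.
#' @export
registrationRecoverySuite <- function(nCases = 10L, seed = 1L,
                                      volumeShape = 128L, spacingUm = 10) {
  scene <- generatePhantom(phantomConfig(volumeShape = volumeShape,
                                         spacingUm = spacingUm,
                                         seed = deriveSeed(seed, "phantom")))
  ctr <- (dim(voxels(sceneImage(scene))) - 1) / 2 * spacingUm
  set.seed(deriveSeed(seed, "transforms"))
  thetas <- stats::runif(nCases, 0, 360)
  scales <- stats::runif(nCases, 0.95, 1.05)
  out <- data.frame(thetaTrueDeg = thetas, scaleTrue = scales,
                    thetaErrDeg = NA_real_, scaleRelErr = NA_real_)
  for (i in seq_len(nCases)) {
    tr <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                              thetaZDeg = thetas[i], scale = scales[i])
    child <- deriveLowerResolution(scene, 2, tr)
    reg <- registerVolumes(sceneImage(child), sceneImage(scene), ctr, ctr)
    tt <- reg$transform
    thTrue <- (-thetas[i]) %% 360  # parent -> child is the inverse map
    thGot <- (tt@thetaZDeg + tt@thetaXYDeg) %% 360
    out$thetaErrDeg[i] <- min(abs(thGot - thTrue), 360 - abs(thGot - thTrue))
    out$scaleRelErr[i] <- abs(tt@scale - 1 / scales[i]) * scales[i]
  }
  out
}

#' Two-level phantom pipeline demonstration
#'
#' Runs the full hierarchical cycle on a synthetic pair: generates a
#' high-resolution phantom, derives a half-resolution copy under a known
#' transform, trains the reference backbone on manually labelled cubes,
#' infers, post-filters, registers, propagates pseudo-labels, fine-tunes at
#' the low level and measures (a) the fraction of ground-truth glomeruli
#' recovered at the lowest level by centroid matching within one low-res
#' voxel and (b) fine-tuned versus scratch-trained validation Dice at equal
#' epochs on the same pseudo-labelled cubes.
#'
#' @param seed root seed for the whole run.
#' @param volumeShape,spacingUm high-resolution phantom geometry.
#' @param thetaZDeg,scale the known child-to-parent transform.
#' @param epochs training epochs per level.
#' @param patchEdge training patch edge (voxels).
#' @return list with \code{recall}, \code{nMatched}, \code{nTruth},
#'   \code{fineTunedValDice}, \code{scratchValDice}, \code{transform}
#'   (recovered), and \code{manifests} for both cycles.
#' @export
phantomTwoLevelDemo <- function(seed = 1L, volumeShape = 160L,
                                spacingUm = 10, thetaZDeg = 25, scale = 1,
                                epochs = 15L, patchEdge = 40L) {
  cfg <- phantomConfig(volumeShape = volumeShape, spacingUm = spacingUm,
                       seed = deriveSeed(seed, "phantom"))
  sceneH <- generatePhantom(cfg)
  dims <- dim(voxels(sceneImage(sceneH)))
  ctr <- (dims - 1) / 2 * spacingUm
  tr <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                            thetaZDeg = thetaZDeg, scale = scale)
  sceneL <- deriveLowerResolution(sceneH, 2, tr)

  # manually labelled cubes: the eight octants of the high-res volume
  half <- dims %/% 2L
  imgH <- voxels(sceneImage(sceneH))
  labH <- labelArray(truthLabels(sceneH))
  cubes <- list(); m <- 0L
  for (k in 0:1) for (j in 0:1) for (i in 0:1) {
    rx <- i * half[1] + seq_len(half[1])
    ry <- j * half[2] + seq_len(half[2])
    rz <- k * half[3] + seq_len(half[3])
    org <- c(i, j, k) * half * spacingUm
    m <- m + 1L
    cubes[[m]] <- annotatedCube(
      volume3d(imgH[rx, ry, rz], spacingUm = spacingUm, originUm = org),
      labelVolume(labH[rx, ry, rz], spacingUm = spacingUm, originUm = org,
                  kind = "instance"),
      cubeId = sprintf("manual-%d", m))
  }

  fixedPoint <- applyTransform(invertTransform(tr), ctr)
  tc <- trainConfig(epochs = epochs, patchEdge = patchEdge, seed = seed)
  lvl0 <- list(levelId = "L0", resolutionLevel = "high",
               image = sceneImage(sceneH), cubes = cubes,
               nextLevel = list(image = sceneImage(sceneL),
                                fixedPointUm = fixedPoint,
                                movingPointUm = ctr,
                                resolutionLevel = "low"))
  c0 <- runCycle(lvl0, trainCfg = tc, rootSeed = seed)
  lvl1 <- list(levelId = "L1", resolutionLevel = "low",
               image = sceneImage(sceneL), cubes = c0$pseudoCubes)
  c1 <- runCycle(lvl1, model = c0$model, trainCfg = tc, rootSeed = seed)

  # centroid matching within one low-res voxel
  props <- computeProperties(c1$instances, sceneImage(sceneL))
  catL <- catalogue(sceneL)
  matched <- 0L
  for (r in seq_len(nrow(catL))) {
    d <- sqrt((props$x_um - catL$x_um[r])^2 +
                (props$y_um - catL$y_um[r])^2 +
                (props$z_um - catL$z_um[r])^2)
    if (length(d) && min(d) <= spacingUm(sceneL)) matched <- matched + 1L
  }

  # fine-tuned vs scratch at equal epochs on the same pseudo cubes
  pc <- c0$pseudoCubes
  set.seed(deriveSeed(seed, "ftsplit"))
  nVal <- max(1L, floor(0.2 * length(pc)))
  valIdx <- sample(seq_along(pc), nVal)
  trainP <- unlist(lapply(pc[-valIdx], extractPatches,
                          patchEdge = patchEdge), recursive = FALSE)
  valP <- unlist(lapply(pc[valIdx], extractPatches,
                        patchEdge = patchEdge), recursive = FALSE)
  ftSeed <- deriveSeed(seed, "ftcompare")
  ft <- trainBackbone(c0$model, trainP, valP, epochs = epochs,
                      seed = ftSeed)
  sc <- trainBackbone(referenceBackbone(), trainP, valP, epochs = epochs,
                      seed = ftSeed)

  list(recall = matched / max(nrow(catL), 1L), nMatched = matched,
       nTruth = nrow(catL),
       fineTunedValDice = max(ft$history$valDiceEma, na.rm = TRUE),
       scratchValDice = max(sc$history$valDiceEma, na.rm = TRUE),
       transform = c0$transform,
       manifests = list(c0$manifest, c1$manifest))
}
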