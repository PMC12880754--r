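# Shared fixtures. The small phantom is expensive enough to build once and
# reuse across test files; memoised per session.

.fixtures <- new.env()

smallPhantom <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- phantomConfig(volumeShape = 96, spacingUm = 10, seed = 42)
    .fixtures$small <- generatePhantom(cfg)
  }
  .fixtures$small
}

# a backbone trained on the small phantom's patches, reused by the
# postfilter and pipeline tests
smallTrainedModel <- function() {
  if (is.null(.fixtures$model)) {
    scene <- smallPhantom()
    cube <- annotatedCube(sceneImage(scene), truthLabels(scene),
                          cubeId = "c1")
    patches <- extractPatches(cube, patchEdge = 32L)
    .fixtures$model <- trainBackbone(referenceBackbone(), patches[1:20],
                                     patches[21:27], epochs = 20,
                                     seed = 7)$model
  }
  .fixtures$model
}

# binary prediction of the trained model on the small phantom
smallPrediction <- function() {
  if (is.null(.fixtures$pred)) {
    scene <- smallPhantom()
    prob <- slidingWindowInfer(smallTrainedModel(), sceneImage(scene),
                               window = 32L)
    .fixtures$pred <- labelVolume(
      array(as.integer(voxels(prob) >= 0.5), dim(voxels(prob))),
      spacingUm = spacingUm(scene), kind = "binary")
  }
  .fixtures$pred
}

binaryTruth <- function(scene) {
  lab <- labelArray(truthLabels(scene))
  labelVolume(array(as.integer(lab > 0), dim(lab)),
              spacingUm = spacingUm(scene), kind = "binary")
}

# rasterise a digital sphere of given radius (voxels) in a cube
digitalSphere <- function(radiusVox, edge = 2 * radiusVox + 11) {
  ctr <- (edge + 1) / 2
  ax <- (seq_len(edge) - ctr)^2
  d2 <- outer(outer(ax, ax, "+"), ax, "+")
  array(as.integer(d2 <= radiusVox^2), c(edge, edge, edge))
}

# constant-intensity cube with labels, as an AnnotatedCube
toyCube <- function(edge = 32L, sampleId = "s", cubeId = "c",
                    labelFrac = 0, seed = 1) {
  set.seed(seed)
  img <- volume3d(array(round(runif(edge^3, 0, 65535)), rep(edge, 3)),
                  spacingUm = 10)
  lab <- array(0L, rep(edge, 3))
  if (labelFrac > 0) {
    n <- round(labelFrac * edge^3)
    lab[sample(edge^3, n)] <- 1L
  }
  annotatedCube(img, labelVolume(lab, spacingUm = 10, kind = "binary"),
                sampleId = sampleId, cubeId = cubeId)
}
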