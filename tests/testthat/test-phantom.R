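test_that("zero target density yields an empty scene", {
  cfg <- phantomConfig(volumeShape = 48, spacingUm = 10,
                       targetCentreDensityPerMm3 = 0,
                       distractorRates = c(fat = 0, clot = 0, tubule = 0),
                       seed = 1)
  scene <- generatePhantom(cfg)
  expect_equal(sum(labelArray(truthLabels(scene))), 0)
  expect_equal(nrow(catalogue(scene)), 0)
})

test_that("phantom generation is deterministic under a fixed seed and varies across seeds", {
  cfg1 <- phantomConfig(volumeShape = 96, spacingUm = 10, seed = 7)
  s1 <- generatePhantom(cfg1)
  s2 <- generatePhantom(cfg1)
  expect_identical(voxels(sceneImage(s1)), voxels(sceneImage(s2)))
  expect_identical(labelArray(truthLabels(s1)), labelArray(truthLabels(s2)))
  cfg2 <- phantomConfig(volumeShape = 96, spacingUm = 10, seed = 8)
  s3 <- generatePhantom(cfg2)
  expect_gt(nrow(catalogue(s1)), 0)
  expect_false(identical(catalogue(s1), catalogue(s3)))
})

test_that("catalogue instances are contiguous, present in the labels, and inside the cortex", {
  scene <- smallPhantom()
  cat <- catalogue(scene)
  lab <- labelArray(truthLabels(scene))
  expect_identical(cat$id, seq_len(nrow(cat)))
  for (id in cat$id)
    expect_gt(sum(lab == id), 0)
  cortex <- regionMask(scene, "cortex")
  sp <- spacingUm(scene)
  for (r in seq_len(nrow(cat))) {
    vi <- round(c(cat$x_um[r], cat$y_um[r], cat$z_um[r]) / sp) + 1
    expect_true(cortex[vi[1], vi[2], vi[3]])
  }
})

test_that("realised centre density tracks the 9.4 per mm^3 target", {
  cfg <- phantomConfig(volumeShape = 256, spacingUm = 5, seed = 3)
  scene <- generatePhantom(cfg)
  cortexVolMm3 <- sum(regionMask(scene, "cortex")) *
    spacingUm(scene)^3 / 1e9
  realised <- nrow(catalogue(scene)) / cortexVolMm3
  expect_lt(abs(realised - 9.4) / 9.4, 0.15)
})

test_that("label fraction of cortex-centred high-res crops sits in the sparse-annotation envelope", {
  cfg <- phantomConfig(seed = 5)  # default config, 192^3 at 5 um
  scene <- generatePhantom(cfg)
  lab <- labelArray(truthLabels(scene)) > 0
  cortexIdx <- which(regionMask(scene, "cortex"))
  dims <- dim(lab)
  set.seed(99)
  fracs <- replicate(30, {
    v <- arrayInd(cortexIdx[sample.int(length(cortexIdx), 1)], dims)
    lo <- pmin(pmax(as.integer(v) - 64L, 1L), dims - 127L)
    crop <- lab[lo[1]:(lo[1] + 127), lo[2]:(lo[2] + 127),
                lo[3]:(lo[3] + 127)]
    mean(crop)
  })
  expect_gte(mean(fracs), 0.005)
  expect_lte(mean(fracs), 0.065)
})

test_that("infeasible geometry is reported explicitly", {
  # inner and outer ellipsoids both engulf the whole volume: the shell has
  # no voxels, so no glomerulus can be placed at a positive density
  expect_error(
    generatePhantom(phantomConfig(volumeShape = 48, spacingUm = 10,
                                  cortexInnerRadiiUm = rep(5600, 3),
                                  cortexOuterRadiiUm = rep(5601, 3),
                                  seed = 1)),
    "infeasible geometry")
})

test_that("downsampling preserves instances and intensity structure", {
  scene <- smallPhantom()
  child <- deriveLowerResolution(scene, 2)
  expect_identical(dim(voxels(sceneImage(child))), c(48L, 48L, 48L))
  # per-instance voxel counts ~ parent/8 within the anti-aliasing tolerance
  labP <- labelArray(truthLabels(scene))
  labC <- labelArray(truthLabels(child))
  cc <- catalogue(child)
  expect_equal(nrow(cc), nrow(catalogue(scene)))
  for (r in seq_len(nrow(cc))) {
    np <- sum(labP == cc$parent_id[r])
    nc <- sum(labC == cc$id[r])
    expect_lt(abs(nc - np / 8) / (np / 8), 0.30)
  }
})

test_that("the recorded child-to-parent transform maps catalogue centres exactly", {
  scene <- smallPhantom()
  ctr <- rep(475, 3)
  tr <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                            thetaZDeg = 37.4, scale = 1.02)
  child <- deriveLowerResolution(scene, 2, tr)
  cc <- catalogue(child)
  pc <- catalogue(scene)
  mapped <- applyTransform(transformToParent(child),
                           as.matrix(cc[, c("x_um", "y_um", "z_um")]))
  parent <- as.matrix(pc[match(cc$parent_id, pc$id),
                         c("x_um", "y_um", "z_um")])
  err <- sqrt(rowSums((mapped - parent)^2))
  expect_lt(max(err), spacingUm(scene))  # within one parent voxel
})

test_that("a constant-intensity image stays constant under downsampling", {
  scene <- smallPhantom()
  const <- scene
  const@image <- volume3d(array(1234, dim(voxels(sceneImage(scene)))),
                          spacingUm = spacingUm(scene))
  child <- deriveLowerResolution(const, 2)
  expect_true(all(voxels(sceneImage(child)) == 1234))
})

test_that("downsampling below 32 voxels per axis is refused", {
  scene <- smallPhantom()  # 96^3
  expect_error(deriveLowerResolution(scene, 4), "below 32")
})
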