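test_that("transforms compose with their inverse to the identity", {
  t <- rigidScaleTransform(centreFixedUm = c(100, 50, 20),
                           centreMovingUm = c(10, 20, 30),
                           thetaZDeg = 123.4, thetaXYDeg = -3.2,
                           scale = 1.07, translationUm = c(5, -8, 2))
  set.seed(1)
  pts <- matrix(runif(30, -500, 500), 10, 3)
  fwd <- applyTransform(t, pts)
  back <- applyTransform(invertTransform(t), fwd)
  expect_lt(max(abs(back - pts)), 1e-6)
  # a known rotation: 90 degrees about z maps +x to +y
  r90 <- rigidScaleTransform(thetaZDeg = 90)
  expect_equal(applyTransform(r90, c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("transform JSON round-trips exactly", {
  t <- rigidScaleTransform(centreFixedUm = c(1.5, 2.25, 3),
                           thetaZDeg = 37.4, scale = 1.05)
  path <- tempfile(fileext = ".json")
  writeTransform(t, path)
  t2 <- readTransform(path)
  expect_equal(t2@thetaZDeg, 37.4)
  expect_equal(t2@scale, 1.05)
  expect_equal(t2@centreFixedUm, c(1.5, 2.25, 3))
})

test_that("mutual information is maximal at self-similarity and symmetric", {
  scene <- smallPhantom()
  v <- sceneImage(scene)
  arr <- array(as.numeric(voxels(v)), dim(voxels(v)))
  selfMI <- mattesMI(arr, arr)
  set.seed(2)
  noise <- array(runif(length(arr), 0, 65535), dim(arr))
  expect_gt(selfMI, mattesMI(arr, noise))
  # rigid probes of the volume score below self-alignment
  probe <- resampleVolume(v, v, rigidScaleTransform(
    centreFixedUm = rep(475, 3), centreMovingUm = rep(475, 3),
    thetaZDeg = 20))
  expect_gt(selfMI, mattesMI(arr, probe))
  # symmetry under identical binning (brute-force histogram transpose)
  b <- array(as.numeric(voxels(v))^0.8, dim(arr))
  expect_lt(abs(mattesMI(arr, b) - mattesMI(b, arr)), 1e-6)
  expect_error(mattesMI(arr, array(NA_real_, dim(arr))), "overlap")
})

test_that("the staged z-searches bracket a known phantom rotation", {
  scene <- smallPhantom()
  ctr <- rep(475, 3)
  tr <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                            thetaZDeg = 37.4)
  child <- deriveLowerResolution(scene, 2, tr)
  # registering parent (moving) onto child (fixed): true angle is -37.4
  mv <- glomscale:::prebinMoving(sceneImage(scene), spacingUm(child))
  coarse <- coarseZSearch(sceneImage(child), mv, ctr, ctr)
  expect_equal(nrow(coarse$trace), 180)
  thTrue <- (-37.4) %% 360
  expect_lte(min(abs(coarse$bestAngle - thTrue),
                 360 - abs(coarse$bestAngle - thTrue)), 2)
  # argmax contract
  expect_equal(coarse$trace$mi[coarse$trace$angle == coarse$bestAngle],
               max(coarse$trace$mi))
  refined <- refineZSearch(sceneImage(child), mv, ctr, ctr,
                           coarse$bestAngle)
  expect_lte(min(abs(refined$bestAngle - thTrue),
                 360 - abs(refined$bestAngle - thTrue)), 0.2)
  # refined angle lies inside the sweep window and cannot be worse
  expect_lte(abs(refined$bestAngle - coarse$bestAngle), 2.5)
  expect_gte(max(refined$trace$mi), max(coarse$trace$mi) - 1e-9)
})

test_that("identity pairs register to zero rotation", {
  scene <- smallPhantom()
  child <- deriveLowerResolution(scene, 2)
  ctr <- rep(475, 3)
  mv <- glomscale:::prebinMoving(sceneImage(scene), spacingUm(child))
  coarse <- coarseZSearch(sceneImage(child), mv, ctr, ctr)
  best <- min(coarse$bestAngle, 360 - coarse$bestAngle)
  expect_lte(best, 2)
})

test_that("pose optimisation recovers scale, never degrades the metric, and respects bounds", {
  scene <- smallPhantom()
  ctr <- rep(475, 3)
  tr <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                            thetaZDeg = 20, scale = 1.05)
  child <- deriveLowerResolution(scene, 2, tr)
  mv <- glomscale:::prebinMoving(sceneImage(scene), spacingUm(child))
  coarse <- coarseZSearch(sceneImage(child), mv, ctr, ctr)
  refined <- refineZSearch(sceneImage(child), mv, ctr, ctr,
                           coarse$bestAngle)
  init <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                              thetaZDeg = refined$bestAngle)
  opt <- optimisePose(sceneImage(child), mv, init)
  expect_gte(opt$finalMI, opt$initMI - 1e-9)
  # true relative scale is 1/1.05; recovered within 1%
  expect_lt(abs(opt$transform@scale - 1 / 1.05) * 1.05, 0.01)
  # true total rotation is -20; recovered within 0.5 degrees here
  thGot <- (opt$transform@thetaZDeg + opt$transform@thetaXYDeg) %% 360
  expect_lt(min(abs(thGot - 340), 360 - abs(thGot - 340)), 0.5)
  expect_gte(opt$transform@scale, 0.8)
  expect_lte(opt$transform@scale, 1.25)
})

test_that("label resampling preserves IDs, supports and identity grids", {
  scene <- smallPhantom()
  lab <- truthLabels(scene)
  same <- resampleLabels(lab, identityTransform(), lab)
  expect_identical(labelArray(same), labelArray(lab))
  # IDs can only decrease under nearest-neighbour resampling
  child <- deriveLowerResolution(scene, 2)
  down <- resampleLabels(lab, identityTransform(),
                         truthLabels(child))
  expect_true(all(unique(as.integer(labelArray(down))) %in%
                    c(0L, unique(as.integer(labelArray(lab))))))
})

test_that("resampled high-res truth lands on low-res truth centroids", {
  scene <- smallPhantom()
  ctr <- rep(475, 3)
  tr <- rigidScaleTransform(centreFixedUm = ctr, centreMovingUm = ctr,
                            thetaZDeg = 55, scale = 1.03)
  child <- deriveLowerResolution(scene, 2, tr)
  # map parent truth into the child frame with the exact inverse transform
  resampled <- resampleLabels(truthLabels(scene),
                              invertTransform(transformToParent(child)),
                              truthLabels(child))
  img <- volume3d(array(0, dim(labelArray(resampled))),
                  spacingUm = spacingUm(child),
                  bitDepth = 0L, originUm = originUm(truthLabels(child)))
  prRes <- computeProperties(resampled, img)
  prTrue <- computeProperties(truthLabels(child), img)
  shared <- intersect(prRes$instance_id, prTrue$instance_id)
  expect_gte(length(shared), 1)
  for (id in shared) {
    a <- prRes[prRes$instance_id == id, c("x_um", "y_um", "z_um")]
    b <- prTrue[prTrue$instance_id == id, c("x_um", "y_um", "z_um")]
    expect_lt(sqrt(sum((a - b)^2)), spacingUm(child))
  }
})

test_that("pseudo-cube tiling covers the overlap with exact label crops", {
  scene <- smallPhantom()
  child <- deriveLowerResolution(scene, 2)  # 48^3
  pred <- resampleLabels(truthLabels(scene), identityTransform(),
                         truthLabels(child))
  cubes <- makePseudoCubes(sceneImage(child), pred, cubeEdge = 24L)
  expect_length(cubes, 8)
  expect_true(all(vapply(cubes, function(cb) cb@provenance, "") == "pseudo"))
  for (cb in cubes) {
    off <- round((originUm(cb@image) - originUm(sceneImage(child))) /
                   spacingUm(child))
    rng <- lapply(off, function(o) o + 1:24)
    expect_identical(labelArray(cb@labels),
                     labelArray(pred)[rng[[1]], rng[[2]], rng[[3]]])
  }
  expect_error(makePseudoCubes(sceneImage(child), pred, cubeEdge = 64L),
               "smaller than one cube")
})

test_that("an empty prediction still yields (empty) pseudo cubes", {
  scene <- smallPhantom()
  child <- deriveLowerResolution(scene, 2)
  empty <- labelVolume(array(0L, dim(voxels(sceneImage(child)))),
                       spacingUm = spacingUm(child), kind = "binary")
  cubes <- makePseudoCubes(sceneImage(child), empty, cubeEdge = 24L)
  expect_length(cubes, 8)
  expect_true(all(vapply(cubes, function(cb)
    sum(labelArray(cb@labels)), numeric(1)) == 0))
})
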