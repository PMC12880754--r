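test_that("Dice matches its definition including the both-empty convention", {
  a <- array(0L, c(4, 4, 4))
  expect_equal(diceScore(a, a), 1)  # both empty -> 1
  b <- a; b[1:2, 1, 1] <- 1L
  expect_equal(diceScore(b, b), 1)
  c <- a; c[3:4, 4, 4] <- 1L
  expect_equal(diceScore(b, c), 0)
  # |P| = |T| = 8 with 4 shared voxels -> 0.5
  p <- a; p[1:8] <- 1L
  t <- a; t[5:12] <- 1L
  expect_equal(diceScore(p, t), 0.5)
  expect_error(diceScore(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))),
               "shape mismatch")
})

test_that("connected components count and order instances as documented", {
  arr <- array(0L, c(20, 20, 20))
  arr[2:4, 2:4, 2:4] <- 1L      # 27 voxels
  arr[10:15, 10:15, 10:15] <- 1L  # 216 voxels
  inst <- labelInstances(labelVolume(arr, kind = "binary"))
  expect_equal(max(labelArray(inst)), 2)
  # IDs ordered by decreasing size: the large block is instance 1
  expect_equal(sum(labelArray(inst) == 1), 216)
  expect_equal(sum(labelArray(inst) == 2), 27)
  # empty volume -> no instances
  expect_equal(max(labelArray(labelInstances(
    labelVolume(array(0L, c(8, 8, 8)), kind = "binary")))), 0)
})

test_that("corner-touching blocks merge under 26- but not 6-connectivity", {
  arr <- array(0L, c(10, 10, 10))
  arr[1:3, 1:3, 1:3] <- 1L
  arr[4:6, 4:6, 4:6] <- 1L  # touches only at the (3,3,3)/(4,4,4) corner
  i26 <- labelInstances(labelVolume(arr, kind = "binary"), connectivity = 26)
  i6 <- labelInstances(labelVolume(arr, kind = "binary"), connectivity = 6)
  expect_equal(max(labelArray(i26)), 1)
  expect_equal(max(labelArray(i6)), 2)
})

test_that("instance properties recover sphere geometry, variance and conventions", {
  sph <- digitalSphere(10)
  inst <- labelVolume(sph, spacingUm = 2, kind = "instance")
  img <- volume3d(array(100, dim(sph)), spacingUm = 2)
  pr <- computeProperties(inst, img)
  expect_equal(nrow(pr), 1)
  # equivalent radius within 5% of 10 voxels x 2 um spacing
  expect_lt(abs(pr$equivalent_radius_um - 20) / 20, 0.05)
  expect_gte(pr$roundness, 0.9)
  expect_equal(pr$intensity_variance, 0)  # constant intensity
  expect_equal(pr$volume_um3, pr$voxel_count * 2^3)
  # single-voxel instance: variance 0, roundness 1 by convention
  one <- array(0L, c(8, 8, 8)); one[4, 4, 4] <- 1L
  pr1 <- computeProperties(labelVolume(one, kind = "instance"),
                           volume3d(array(runif(512), c(8, 8, 8)),
                                    bitDepth = 0L))
  expect_equal(pr1$intensity_variance, 0)
  expect_equal(pr1$roundness, 1)
})

test_that("an instance of 1e6 um^3 has a 62 um equivalent radius", {
  # 1e6 um^3 at 10 um spacing = 1000 voxels
  arr <- array(0L, c(12, 12, 12))
  arr[1:10, 1:10, 1:10] <- 1L
  pr <- computeProperties(labelVolume(arr, spacingUm = 10,
                                      kind = "instance"),
                          volume3d(array(0, c(12, 12, 12)), spacingUm = 10,
                                   bitDepth = 0L))
  expect_equal(pr$volume_um3, 1e6)
  expect_equal(round(pr$equivalent_radius_um), 62)
})

test_that("neighbourhood counts use the W-voxel window including self", {
  tab <- data.frame(instance_id = 1, x_um = 0, y_um = 0, z_um = 0)
  expect_equal(neighbourhoodCount(tab, 64, 1)$neighbour_count, 1)
  tab3 <- data.frame(instance_id = 1:3, x_um = c(0, 10, 20),
                     y_um = 0, z_um = 0)
  expect_equal(neighbourhoodCount(tab3, 64, 1)$neighbour_count, rep(3L, 3))
  # centroids on a regular 64-voxel grid with W = 128: interior counts 27
  g <- expand.grid(x = 0:4, y = 0:4, z = 0:4) * 64
  tabG <- data.frame(instance_id = seq_len(nrow(g)), x_um = g$x,
                     y_um = g$y, z_um = g$z)
  cnt <- neighbourhoodCount(tabG, 128, 1)$neighbour_count
  interior <- g$x %in% c(64, 128, 192) & g$y %in% c(64, 128, 192) &
    g$z %in% c(64, 128, 192)
  expect_true(all(cnt[interior] == 27))
  # brute-force oracle on the full grid
  brute <- vapply(seq_len(nrow(g)), function(r)
    sum(abs(g$x - g$x[r]) <= 64 & abs(g$y - g$y[r]) <= 64 &
          abs(g$z - g$z[r]) <= 64), integer(1))
  expect_identical(as.integer(cnt), brute)
})

test_that("the radius floor keeps 63 um instances and removes 61 um ones", {
  mkBall <- function(radiusUm, at, arr, sp = 4) {
    d <- dim(arr)
    ax <- ((seq_len(d[1]) - at[1]) * sp)^2
    ay <- ((seq_len(d[2]) - at[2]) * sp)^2
    az <- ((seq_len(d[3]) - at[3]) * sp)^2
    arr[outer(outer(ax, ay, "+"), az, "+") <= radiusUm^2] <- 1L
    arr
  }
  arr <- array(0L, c(80, 40, 40))
  arr <- mkBall(61, c(20, 20, 20), arr)
  arr <- mkBall(63, c(60, 20, 20), arr)
  inst <- labelInstances(labelVolume(arr, spacingUm = 4, kind = "binary"))
  img <- volume3d(array(0, dim(arr)), spacingUm = 4, bitDepth = 0L)
  pr <- computeProperties(inst, img)
  expect_equal(nrow(pr), 2)
  filtered <- applyThresholdSet(inst, pr, thresholdSet())
  keptIds <- unique(labelArray(filtered)[labelArray(filtered) > 0])
  keptR <- pr$equivalent_radius_um[pr$instance_id %in% keptIds]
  expect_length(keptIds, 1)
  expect_gt(keptR, 62)
})

test_that("filtering is monotone in each threshold and identity when inactive", {
  scene <- smallPhantom()
  pred <- smallPrediction()
  inst <- labelInstances(pred)
  pr <- computeProperties(inst, sceneImage(scene),
                          cortexMask = regionMask(scene, "cortex"))
  none <- thresholdSet(radiusMinUm = NA)  # all criteria inactive
  noneOut <- applyThresholdSet(inst, pr, none)
  expect_identical(labelArray(noneOut), labelArray(inst))
  expect_equal(nrow(pr), max(labelArray(inst)))
  nKept <- function(th) {
    out <- labelArray(applyThresholdSet(inst, pr, th))
    length(unique(out[out > 0]))
  }
  # tightening any single threshold never increases the kept count
  for (vl in quantile(pr$intensity_variance, c(0.1, 0.5, 0.9))) {
    expect_lte(nKept(thresholdSet(varianceLower = vl, radiusMinUm = NA)),
               nKept(thresholdSet(radiusMinUm = NA)))
  }
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95), function(q)
    nKept(thresholdSet(roundnessMin = q, radiusMinUm = NA)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  counts2 <- vapply(c(40, 62, 80, 100), function(r)
    nKept(thresholdSet(radiusMinUm = r)), numeric(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("near-zero-variance fat blobs are removed while cortical glomeruli survive", {
  scene <- smallPhantom()
  pred <- smallPrediction()
  inst <- labelInstances(pred)
  pr <- computeProperties(inst, sceneImage(scene),
                          cortexMask = regionMask(scene, "cortex"))
  # the fat distractor is bright but textureless: variance far below glomeruli
  glomVar <- pr$intensity_variance[pr$in_cortex]
  fatVar <- pr$intensity_variance[!pr$in_cortex]
  expect_gte(length(fatVar), 1)
  expect_lt(max(fatVar), min(glomVar))
  th <- thresholdSet(varianceLower = sqrt(max(fatVar) * min(glomVar)),
                     radiusMinUm = NA)
  kept <- labelArray(applyThresholdSet(inst, pr, th))
  keptIds <- unique(kept[kept > 0])
  expect_true(all(pr$in_cortex[pr$instance_id %in% keptIds]))
})

test_that("watershed splitting separates touching spheres and leaves singles alone", {
  mkBall <- function(arr, at, rVox) {
    d <- dim(arr)
    ax <- (seq_len(d[1]) - at[1])^2
    ay <- (seq_len(d[2]) - at[2])^2
    az <- (seq_len(d[3]) - at[3])^2
    arr[outer(outer(ax, ay, "+"), az, "+") <= rVox^2] <- 1L
    arr
  }
  # two spheres of radius 5 voxels (100 um at 20 um/voxel) whose surfaces
  # touch: one 26-connected component, two distance-transform cores
  arr <- array(0L, c(40, 20, 20))
  arr <- mkBall(arr, c(12, 10, 10), 5)
  arr <- mkBall(arr, c(22, 10, 10), 5)
  inst <- labelInstances(labelVolume(arr, spacingUm = 20, kind = "binary"))
  expect_equal(max(labelArray(inst)), 1)
  split <- splitTouchingInstances(inst)
  expect_equal(max(labelArray(split)), 2)
  # centroids land near the two sphere centres
  img <- volume3d(array(0, dim(arr)), spacingUm = 20, bitDepth = 0L)
  pr <- computeProperties(split, img)
  got <- sort(pr$x_um)
  expect_lt(abs(got[1] - 11 * 20), 20)
  expect_lt(abs(got[2] - 21 * 20), 20)
  # voxel conservation: splitting reassigns, never discards
  expect_equal(sum(labelArray(split) > 0), sum(arr))
  # an isolated sphere passes through unchanged
  one <- array(0L, c(20, 20, 20))
  one <- mkBall(one, c(10, 10, 10), 5)
  instOne <- labelInstances(labelVolume(one, spacingUm = 20,
                                        kind = "binary"))
  splitOne <- splitTouchingInstances(instOne)
  expect_identical(labelArray(splitOne) > 0, labelArray(instOne) > 0)
  expect_equal(max(labelArray(splitOne)), 1)
})

test_that("requesting the cortex criterion without a mask errors", {
  arr <- array(0L, c(8, 8, 8)); arr[2:4, 2:4, 2:4] <- 1L
  inst <- labelInstances(labelVolume(arr, kind = "binary"))
  pr <- computeProperties(inst, volume3d(array(0, c(8, 8, 8)),
                                         bitDepth = 0L))
  expect_error(applyThresholdSet(inst, pr,
                                 thresholdSet(useCortexMask = TRUE)),
               "cortex mask")
})

test_that("LHS candidates stratify every tunable dimension exactly", {
  scene <- smallPhantom()
  pred <- smallPrediction()
  ev <- list(list(prediction = pred, truth = binaryTruth(scene),
                  image = sceneImage(scene),
                  cortexMask = regionMask(scene, "cortex")))
  res <- lhsSearch(ev, seed = 3)
  u <- res$samples
  expect_equal(nrow(u), 20)
  for (j in seq_len(ncol(u)))
    expect_length(unique(floor(u[, j] * 20)), 20)
  expect_length(res$candidates, 20)
})

test_that("collapsed percentile intervals deactivate their parameter", {
  # all instances identical -> degenerate property distributions
  arr <- array(0L, c(40, 16, 16))
  arr[2:5, 2:5, 2:5] <- 1L
  arr[22:25, 2:5, 2:5] <- 1L
  inst <- labelVolume(arr, kind = "binary")
  img <- volume3d(array(100, dim(arr)), bitDepth = 0L)
  truth <- labelVolume(arr, kind = "binary")
  res <- lhsSearch(list(list(prediction = inst, truth = truth, image = img)),
                   seed = 1)
  # variance is 0 for both instances: variance thresholds must be inactive
  expect_true(all(vapply(res$candidates, function(th)
    is.na(th@varianceLower) && is.na(th@varianceUpper), logical(1))))
  # identical candidates score identically
  expect_equal(length(unique(round(res$scores, 12))), 1)
})

test_that("the LHS-selected thresholds beat the unfiltered prediction", {
  scene <- smallPhantom()
  pred <- smallPrediction()
  ev <- list(list(prediction = pred, truth = binaryTruth(scene),
                  image = sceneImage(scene),
                  cortexMask = regionMask(scene, "cortex")))
  res <- lhsSearch(ev, seed = 3)
  expect_gt(res$scores[res$best], mean(res$unfilteredDice))
})

test_that("published reference thresholds load with the documented structure", {
  ref <- referenceThresholds()
  expect_named(ref, c("high", "intermediate", "low"))
  expect_equal(ref$high@varianceLower, 114770.713)
  expect_equal(ref$high@roundnessMin, 0.709)
  expect_equal(ref$low@radiusMinUm, 62)
  expect_true(ref$low@useCortexMask)
  expect_equal(ref$intermediate@densityWindowW, 128)
  expect_equal(ref$intermediate@densityMinCount, 3)
})
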