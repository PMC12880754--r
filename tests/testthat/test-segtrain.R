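test_that("combined loss matches its closed forms at the contract points", {
  cfg <- lossConfig()
  n <- 64
  # perfect prediction: Dice term < 1e-4, CE ~ 1e-7
  p <- rep(1 - 1e-7, n)
  q <- rep(1, n)
  ce <- -mean(log(p))
  dice <- 1 - (2 * sum(p) + cfg$eps1) / (sum(p) + n + cfg$eps2)
  expect_lt(dice, 1e-4)
  expect_equal(combinedLoss(p, q, cfg), ce + dice)
  # uniform 0.5 on an empty target: Dice loss = 1 - eps1/(sum(p) + eps2)
  p2 <- rep(0.5, n)
  q2 <- rep(0, n)
  expected_dice <- 1 - cfg$eps1 / (sum(p2) + cfg$eps2)
  expect_equal(combinedLoss(p2, q2, cfg),
               -mean(log(1 - p2)) + expected_dice)
  expect_gt(expected_dice, 0.99)
  # beta = 0 reduces to plain cross-entropy
  set.seed(1)
  p3 <- runif(n, 0.01, 0.99)
  q3 <- rbinom(n, 1, 0.3)
  expect_equal(combinedLoss(p3, q3, lossConfig(beta = 0)),
               -mean(q3 * log(p3) + (1 - q3) * log(1 - p3)))
})

test_that("combined loss rejects malformed inputs", {
  expect_error(combinedLoss(rep(0.5, 8), rep(1, 9)), "shapes differ")
  expect_error(combinedLoss(c(0, 0.5), c(1, 1)), "in \\(0, 1\\)")
})

test_that("combined loss decreases monotonically from wrong to correct predictions", {
  set.seed(4)
  q <- array(rbinom(512, 1, 0.2), c(8, 8, 8))
  wrong <- 0.9 * (1 - q) + 0.05
  right <- 0.9 * q + 0.05
  ts <- seq(0, 1, length.out = 11)
  losses <- vapply(ts, function(t)
    combinedLoss((1 - t) * wrong + t * right, q, lossConfig()), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("EMA tracking follows the first-epoch rule, the recursion and its fixed point", {
  t1 <- emaUpdate(emaTracker(), 0.7)
  expect_equal(emaValue(t1), 0.7)
  t2 <- emaUpdate(emaTracker(), 0.5)
  expect_equal(emaValue(emaUpdate(t2, 0.9)), 0.54)
  # constant sequence is a fixed point
  tc <- emaTracker()
  for (i in 1:25) tc <- emaUpdate(tc, 0.625)
  expect_equal(emaValue(tc), 0.625)
  # bounded by observed extremes
  set.seed(5)
  vals <- runif(50)
  tr <- emaTracker()
  for (v in vals) tr <- emaUpdate(tr, v)
  expect_gte(emaValue(tr), min(vals))
  expect_lte(emaValue(tr), max(vals))
})

test_that("EMA value is insensitive to input representation precision", {
  set.seed(6)
  vals <- runif(40)
  t1 <- emaTracker(); t2 <- emaTracker()
  for (v in vals) {
    t1 <- emaUpdate(t1, v)
    t2 <- emaUpdate(t2, signif(v, 8))  # float32-level rounding
  }
  expect_lt(abs(emaValue(t1) - emaValue(t2)), 1e-6)
})

test_that("cross-validation folds partition the cubes and are reproducible", {
  cubes <- lapply(1:5, function(i)
    toyCube(edge = 16L, cubeId = paste0("c", i), labelFrac = 0.05, seed = i))
  cfg <- trainConfig(nFolds = 5, epochs = 2, patchEdge = 16L, seed = 9)
  rep1 <- runCV(cubes, cfg = cfg)
  expect_identical(sort(unique(rep1$foldAssignment)), 1:5)
  expect_identical(tabulate(rep1$foldAssignment, 5), rep(1L, 5))
  rep2 <- runCV(cubes, cfg = cfg)
  expect_identical(rep1$foldAssignment, rep2$foldAssignment)
  expect_identical(rep1$models[[1]]$weights, rep2$models[[1]]$weights)
  expect_true(all(rep1$history$valDice >= 0 & rep1$history$valDice <= 1,
                  na.rm = TRUE))
  expect_error(runCV(cubes[1:3], cfg = cfg), "fewer cubes than folds")
})

test_that("cross-validated training on the phantom beats the all-background baseline", {
  scene <- smallPhantom()
  cube <- annotatedCube(sceneImage(scene), truthLabels(scene), cubeId = "c")
  # split the 96^3 phantom into 8 cubes of 48^3
  cubes <- list(); m <- 0
  for (k in 0:1) for (j in 0:1) for (i in 0:1) {
    rx <- i * 48 + 1:48; ry <- j * 48 + 1:48; rz <- k * 48 + 1:48
    m <- m + 1
    cubes[[m]] <- annotatedCube(
      volume3d(voxels(sceneImage(scene))[rx, ry, rz], spacingUm = 10),
      labelVolume(labelArray(truthLabels(scene))[rx, ry, rz],
                  spacingUm = 10, kind = "instance"),
      cubeId = paste0("c", m))
  }
  rep <- runCV(cubes, cfg = trainConfig(nFolds = 2, epochs = 15,
                                        patchEdge = 24L, seed = 2))
  # the all-background constant prediction scores Dice 0 on any non-empty
  # validation fold; the trained model must clear it by a real margin
  expect_gt(rep$meanValDice, 0.15)
})

test_that("sliding-window blend weights sum to one and degenerate cases hold", {
  zero <- referenceBackbone()
  zero$weights <- c(-50, 0, 0, 0, 0, 0)  # constant-background model
  v <- volume3d(array(round(runif(48^3, 0, 65535)), c(48, 48, 48)),
                spacingUm = 10)
  out <- slidingWindowInfer(zero, v, window = 32L, overlapFraction = 0.5)
  expect_identical(dim(voxels(out)), dim(voxels(v)))
  expect_true(all(voxels(out) < 1e-10))
  # single window: output equals the direct model output
  v1 <- volume3d(array(round(runif(32^3, 0, 65535)), c(32, 32, 32)),
                 spacingUm = 10)
  model <- smallTrainedModel()
  direct <- predictPatch(model, v1)
  sw <- slidingWindowInfer(model, v1, window = 32L)
  expect_equal(voxels(sw), direct)
  # overlapping-window averages stay inside [0, 1] (weights sum to 1)
  sw2 <- slidingWindowInfer(model, v, window = 32L, overlapFraction = 0.5)
  expect_true(all(voxels(sw2) >= 0 & voxels(sw2) <= 1))
})

test_that("pseudo-cube retention follows the stated empty/low-density rules", {
  empty <- lapply(1:1000, function(i) toyCube(edge = 8L, labelFrac = 0,
                                              cubeId = paste0("e", i)))
  full <- lapply(1:50, function(i) toyCube(edge = 8L, labelFrac = 0.2,
                                           cubeId = paste0("f", i), seed = i))
  kept <- filterTrainingCubes(c(empty, full), level = "intermediate",
                              seed = 1)
  # 50 non-empty + round-half-up(1000 * 1.05%) = 50 + 11
  expect_length(kept, 61)
  # no empty pool: identity
  expect_length(filterTrainingCubes(full, level = "intermediate"), 50)
  # low level with all densities >= 1%: rule is vacuous
  expect_length(filterTrainingCubes(full, level = "low"), 50)
  # determinism
  k2 <- filterTrainingCubes(c(empty, full), level = "intermediate", seed = 1)
  expect_identical(vapply(kept, function(cb) cb@cubeId, ""),
                   vapply(k2, function(cb) cb@cubeId, ""))
})

test_that("fine-tuning is a no-op at zero epochs and deterministic under a seed", {
  model <- smallTrainedModel()
  cubes <- list(toyCube(edge = 16L, labelFrac = 0.05, seed = 1))
  same <- fineTune(model, cubes, trainConfig(epochs = 0, patchEdge = 16L,
                                             mode = "finetune"))
  expect_identical(same$model$weights, model$weights)
  cfg <- trainConfig(epochs = 3, patchEdge = 16L, seed = 4,
                     mode = "finetune")
  f1 <- fineTune(model, cubes, cfg)
  f2 <- fineTune(model, cubes, cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_false(identical(f1$model$weights, model$weights))
})
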