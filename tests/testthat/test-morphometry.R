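test_that("the summation-kernel density map conserves counts and hits the closed-form peak", {
  dm <- densityMap(matrix(c(16, 16, 16), 1), c(31, 31, 31),
                   kernelEdge = 31, spacingUm = 25.08)
  expect_equal(sum(dm$counts), 31^3)
  expect_true(all(dm$counts %in% c(0, 1)))
  # peak per-mm^3 density for one centre: 1 / (31 x 0.02508 mm)^3
  expect_equal(max(dm$perMm3), 1 / (31 * 0.02508 / 1000 * 1000)^3,
               tolerance = 1e-10)
  expect_equal(round(max(dm$perMm3), 2), 2.13)
  # N well-separated interior centres conserve N x 31^3
  ctrs <- rbind(c(20, 20, 20), c(80, 80, 80), c(20, 80, 50))
  dm3 <- densityMap(ctrs, c(100, 100, 100), 31, 10)
  expect_equal(sum(dm3$counts), 3 * 31^3)
  expect_error(densityMap(matrix(c(200, 1, 1), 1), c(50, 50, 50)),
               "inside the grid")
})

test_that("slab zonation yields the analytic 30/40/30 band proportions", {
  dims <- c(20, 20, 60)
  med <- array(FALSE, dims); med[, , 1:10] <- TRUE
  cx <- array(FALSE, dims); cx[, , 11:50] <- TRUE  # 2000 um at 50 um/voxel
  zp <- zonateCortex(cx, med, meanDiameterUm = 200, spacingUm = 50)
  tot <- sum(cx)
  expect_equal(sum(zp@inner) / tot, 0.30)
  expect_equal(sum(zp@middle) / tot, 0.40)
  expect_equal(sum(zp@outer) / tot, 0.30)
  expect_equal(sum(zp@inner) + sum(zp@middle) + sum(zp@outer), tot)
})

test_that("thin cortex collapses the middle zone with inner precedence", {
  dims <- c(10, 10, 40)
  med <- array(FALSE, dims); med[, , 1:10] <- TRUE
  cx <- array(FALSE, dims); cx[, , 11:30] <- TRUE  # 1000 um thick
  expect_warning(zp <- zonateCortex(cx, med, 200, 50), "middle zone")
  expect_equal(sum(zp@middle), 0)
  expect_equal(sum(zp@inner) + sum(zp@outer), sum(cx))
  # the overlap region is claimed by the inner band
  expect_gt(sum(zp@inner), sum(zp@outer))
})

test_that("zonation of phantom masks is an exact partition of the cortex", {
  for (seed in c(1, 2)) {
    cfg <- phantomConfig(volumeShape = 48, spacingUm = 20, seed = seed)
    scene <- generatePhantom(cfg)
    cx <- regionMask(scene, "cortex")
    zp <- suppressWarnings(
      zonateCortex(cx, regionMask(scene, "medulla"), 200,
                   spacingUm(scene)))
    expect_equal(sum(zp@inner) + sum(zp@middle) + sum(zp@outer), sum(cx))
    expect_false(any(zp@inner & zp@middle))
    expect_false(any(zp@inner & zp@outer))
    expect_false(any(zp@middle & zp@outer))
  }
})

test_that("zonal statistics aggregate counts, volumes and the zonal test", {
  dims <- c(20, 20, 60)
  med <- array(FALSE, dims); med[, , 1:10] <- TRUE
  cx <- array(FALSE, dims); cx[, , 11:50] <- TRUE
  zp <- zonateCortex(cx, med, 200, 50)
  # three instances, one per zone (z voxel 15 inner, 30 middle, 45 outer)
  tab <- data.frame(instance_id = 1:3, x_um = 500, y_um = 500,
                    z_um = c(15, 30, 45) * 50 - 50,
                    volume_um3 = c(4e6, 5e6, 3e6),
                    equivalent_radius_um = c(98, 106, 89))
  zs <- zonalStats(tab, zp)
  expect_equal(zs$zones$count, c(1L, 1L, 1L))
  expect_equal(zs$zones$median_volume_um3, c(4e6, 5e6, 3e6))
  expect_equal(zs$meanDiameterUm, 2 * mean(tab$equivalent_radius_um))
  expect_equal(zs$cortexVolumeCm3, sum(cx) * 50^3 / 1e12)
  # all instances in the middle zone: inner/outer report zero counts, NA stats
  tabM <- tab; tabM$z_um <- rep(30 * 50 - 50, 3)
  zsM <- zonalStats(tabM, zp)
  expect_equal(zsM$zones$count, c(0L, 3L, 0L))
  expect_true(is.na(zsM$zones$median_volume_um3[1]))
  expect_true(is.na(zsM$kruskal["H"]))
})

test_that("Kruskal-Wallis matches the hand formula and the trivial cases", {
  kw <- kruskalWallis(list(1:3, 4:6, 7:9))
  # hand computation: 12/90 * (12 + 75 + 192) - 30 = 7.2
  expect_equal(unname(kw["H"]), 7.2)
  expect_equal(unname(kw["p"]),
               stats::pchisq(7.2, df = 2, lower.tail = FALSE))
  # identical groups: H = 0 (all ties), p = 1
  kw0 <- kruskalWallis(list(rep(5, 4), rep(5, 4), rep(5, 4)))
  expect_equal(unname(kw0["H"]), 0)
  expect_equal(unname(kw0["p"]), 1)
  expect_error(kruskalWallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis p agrees with a permutation null on shifted zone data", {
  set.seed(10)
  g <- list(rlnorm(60, log(3e6), 0.25), rlnorm(60, log(3.6e6), 0.25),
            rlnorm(60, log(4.3e6), 0.25))
  kw <- kruskalWallis(g)
  expect_lt(unname(kw["p"]), 0.001)
  # permutation oracle for a weaker (non-saturated) contrast
  set.seed(11)
  g2 <- list(rnorm(15, 0), rnorm(15, 0.5), rnorm(15, 1))
  kw2 <- kruskalWallis(g2)
  values <- unlist(g2)
  lens <- lengths(g2)
  statOf <- function(v) {
    r <- rank(v)
    spl <- split(r, rep(seq_along(lens), lens))
    n <- length(v)
    12 / (n * (n + 1)) * sum(vapply(spl, function(x)
      sum(x)^2 / length(x), numeric(1))) - 3 * (n + 1)
  }
  perm <- replicate(4000, statOf(sample(values)))
  pPerm <- mean(perm >= unname(kw2["H"]))
  expect_lt(abs(pPerm - unname(kw2["p"])),
            0.1 * max(unname(kw2["p"]), pPerm))
})

test_that("uniformly sized phantom glomeruli show no spurious zonal volume effect", {
  # identical lognormal volume distributions in every zone: the zonal test
  # should stay non-significant in the vast majority of draws
  set.seed(12)
  pvals <- replicate(20, {
    g <- lapply(1:3, function(i) rlnorm(50, log(4e6), 0.2))
    unname(kruskalWallis(g)["p"])
  })
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("sphere geometry identities hold in both directions", {
  expect_equal(round(sphereRadiusFromVolume(1e6)), 62)
  expect_equal(signif(sphereVolumeFromRadius(72), 2), 1.6e6)
  expect_equal(sphereRadiusFromVolume(4 * pi / 3), 1)
  expect_equal(sphereVolumeFromRadius(sphereRadiusFromVolume(123)), 123)
  expect_error(sphereRadiusFromVolume(0), "positive")
  expect_error(sphereVolumeFromRadius(-1), "positive")
})
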