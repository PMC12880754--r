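#' Configure a synthetic multiscale kidney phantom
#'
#' The phantom emulates the statistical structure of high-resolution
#' phase-contrast kidney volumes: an ellipsoidal cortical shell around a
#' medulla, glomeruli rendered as bright quasi-spheres of ~200 um mean
#' diameter placed by hard-core rejection sampling at a mean centre density
#' of 9.4 per mm^3 of cortex, plus distractor structures (uniform fat blobs
#' in the capsule rim, very bright high-variance clots in the medulla and
#' elongated tubule segments in the cortex) that mimic the dominant
#' false-positive classes. Intensities are class means plus Gaussian
#' texture and global noise in a 16-bit range.
#'
#' @param volumeShape voxels per axis (length 1 or 3).
#' @param spacingUm micrometres per voxel.
#' @param glomerulusMeanDiameterUm mean glomerular diameter (default 200 um).
#' @param glomerulusDiameterSdFrac lognormal diameter jitter fraction
#'   (default 0.15).
#' @param targetCentreDensityPerMm3 centre density per mm^3 cortex
#'   (default 9.4).
#' @param cortexInnerRadiiUm,cortexOuterRadiiUm semi-axes (um) of the shell;
#'   defaults scale with the volume extent.
#' @param capsuleThicknessUm fat/capsule rim thickness (default 80 um).
#' @param distractorRates named counts per mm^3 of host region
#'   (fat, clot, tubule).
#' @param intensityModel named list of c(mean, sd) per tissue class.
#' @param noiseSd global additive Gaussian noise sd (16-bit units).
#' @param seed integer RNG seed.
#' @return a \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(volumeShape = 64, spacingUm = 10, seed = 1)
#' @export
phantomConfig <- function(volumeShape = c(192L, 192L, 192L), spacingUm = 5,
                          glomerulusMeanDiameterUm = 200,
                          glomerulusDiameterSdFrac = 0.15,
                          targetCentreDensityPerMm3 = 9.4,
                          cortexInnerRadiiUm = NULL,
                          cortexOuterRadiiUm = NULL,
                          capsuleThicknessUm = 80,
                          distractorRates = c(fat = 3, clot = 2, tubule = 3),
                          intensityModel = NULL, noiseSd = 400,
                          seed = 1L) {
  if (length(volumeShape) == 1L) volumeShape <- rep(volumeShape, 3L)
  extent <- volumeShape * spacingUm
  if (is.null(cortexOuterRadiiUm))
    cortexOuterRadiiUm <- extent / 2 * c(0.96, 0.92, 0.88)
  if (is.null(cortexInnerRadiiUm))
    cortexInnerRadiiUm <- cortexOuterRadiiUm * 0.5
  if (is.null(intensityModel))
    intensityModel <- list(
      background = c(3000, 300), medulla = c(21000, 1200),
      cortex = c(26000, 1500), capsule = c(12000, 800),
      glomerulus = c(45000, 4500), fat = c(44000, 15),
      clot = c(58000, 12000), tubule = c(43000, 4000))
  new("PhantomConfig", volumeShape = as.integer(volumeShape),
      spacingUm = as.numeric(spacingUm),
      glomerulusMeanDiameterUm = as.numeric(glomerulusMeanDiameterUm),
      glomerulusDiameterSdFrac = as.numeric(glomerulusDiameterSdFrac),
      targetCentreDensityPerMm3 = as.numeric(targetCentreDensityPerMm3),
      cortexInnerRadiiUm = as.numeric(cortexInnerRadiiUm),
      cortexOuterRadiiUm = as.numeric(cortexOuterRadiiUm),
      capsuleThicknessUm = as.numeric(capsuleThicknessUm),
      distractorRates = distractorRates,
      intensityModel = intensityModel,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("catalogue", "PhantomScene", function(object, ...) object@catalogue)

#' @rdname accessors
#' @export
setMethod("distractors", "PhantomScene", function(object, ...) object@distractors)

#' @rdname accessors
#' @export
setMethod("truthLabels", "PhantomScene", function(object, ...) object@truthLabels)

#' @rdname accessors
#' @export
setMethod("sceneImage", "PhantomScene", function(object, ...) object@image)

#' @rdname accessors
#' @export
setMethod("regionMask", "PhantomScene", function(object, which, ...) {
  if (!which %in% names(object@regionMasks))
    stop("unknown region mask: ", which)
  object@regionMasks[[which]]
})

#' @rdname accessors
#' @export
setMethod("transformToParent", "PhantomScene",
          function(object, ...) object@transformToParent)

#' @rdname accessors
#' @export
setMethod("spacingUm", "PhantomScene",
          function(object, ...) spacingUm(object@image))

setMethod("show", "PhantomScene", function(object) {
  d <- dim(voxels(object@image))
  cat(sprintf("PhantomScene %d x %d x %d, %.3g um/voxel\n", d[1], d[2], d[3],
              spacingUm(object@image)))
  cat(sprintf("  %d glomeruli, %d distractors\n", nrow(object@catalogue),
              nrow(object@distractors)))
})

# normalised ellipsoid coordinate grids for mask construction
ellipsoidField <- function(dims, spacingUm, centreUm, radiiUm) {
  ax <- ((seq_len(dims[1]) - 1) * spacingUm - centreUm[1]) / radiiUm[1]
  ay <- ((seq_len(dims[2]) - 1) * spacingUm - centreUm[2]) / radiiUm[2]
  az <- ((seq_len(dims[3]) - 1) * spacingUm - centreUm[3]) / radiiUm[3]
  outer(outer(ax^2, ay^2, "+"), az^2, "+")
}

fillSphere <- function(dims, spacingUm, centreUm, radiusUm) {
  # returns integer bbox ranges and the logical in-sphere mask for the bbox
  lo <- pmax(1L, floor((centreUm - radiusUm) / spacingUm) + 1L)
  hi <- pmin(dims, ceiling((centreUm + radiusUm) / spacingUm) + 1L)
  if (any(lo > hi)) return(NULL)
  dx <- ((lo[1]:hi[1]) - 1) * spacingUm - centreUm[1]
  dy <- ((lo[2]:hi[2]) - 1) * spacingUm - centreUm[2]
  dz <- ((lo[3]:hi[3]) - 1) * spacingUm - centreUm[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  list(lo = lo, hi = hi, mask = d2 <= radiusUm^2)
}

fillCylinder <- function(dims, spacingUm, p0, p1, radiusUm) {
  lo <- pmax(1L, floor((pmin(p0, p1) - radiusUm) / spacingUm) + 1L)
  hi <- pmin(dims, ceiling((pmax(p0, p1) + radiusUm) / spacingUm) + 1L)
  if (any(lo > hi)) return(NULL)
  gx <- ((lo[1]:hi[1]) - 1) * spacingUm
  gy <- ((lo[2]:hi[2]) - 1) * spacingUm
  gz <- ((lo[3]:hi[3]) - 1) * spacingUm
  nb <- c(length(gx), length(gy), length(gz))
  X <- array(rep(gx, times = nb[2] * nb[3]), nb)
  Y <- array(rep(rep(gy, each = nb[1]), times = nb[3]), nb)
  Z <- array(rep(gz, each = nb[1] * nb[2]), nb)
  d <- p1 - p0
  len2 <- sum(d^2)
  tpar <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
  tpar <- pmin(pmax(tpar, 0), 1)
  dist2 <- (X - (p0[1] + tpar * d[1]))^2 + (Y - (p0[2] + tpar * d[2]))^2 +
    (Z - (p0[3] + tpar * d[3]))^2
  list(lo = lo, hi = hi, mask = dist2 <= radiusUm^2)
}

paintRegion <- function(target, fill, value) {
  # paint `value` into target at the bbox/mask returned by fillSphere/Cylinder
  sub <- target[fill$lo[1]:fill$hi[1], fill$lo[2]:fill$hi[2],
                fill$lo[3]:fill$hi[3], drop = FALSE]
  sub[fill$mask] <- value
  target[fill$lo[1]:fill$hi[1], fill$lo[2]:fill$hi[2],
         fill$lo[3]:fill$hi[3]] <- sub
  target
}

#' Generate a synthetic kidney phantom with known ground truth
#'
#' Glomeruli are placed by hard-core (no-overlap) rejection sampling inside
#' the cortical shell; the instance count is the rounded product of the
#' target centre density and the realised cortex volume, so the realised
#' density tracks the target up to rounding. Distractors are placed in their
#' host regions. The image is rendered as per-class mean intensity plus
#' Gaussian class texture and global noise, clipped to the 16-bit range.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return a \linkS4class{PhantomScene}.
#' @examples
#' scene <- generatePhantom(phantomConfig(volumeShape = 64, spacingUm = 10))
#' nrow(catalogue(scene))
#' @export
generatePhantom <- function(config) {
  validObject(config)
  set.seed(config@seed)
  dims <- config@volumeShape
  sp <- config@spacingUm
  centre <- (dims - 1) / 2 * sp
  im <- config@intensityModel

  fOuter <- ellipsoidField(dims, sp, centre, config@cortexOuterRadiiUm)
  fInner <- ellipsoidField(dims, sp, centre, config@cortexInnerRadiiUm)
  fCaps <- ellipsoidField(dims, sp, centre,
                          config@cortexOuterRadiiUm + config@capsuleThicknessUm)
  medulla <- fInner <= 1
  cortex <- fOuter <= 1 & !medulla
  capsule <- fCaps <= 1 & !medulla & !cortex

  cortexVolMm3 <- sum(cortex) * sp^3 / 1e9
  if (config@targetCentreDensityPerMm3 > 0 && sum(cortex) == 0)
    stop("infeasible geometry: cortical shell contains no voxels at the ",
         "requested density")
  nTarget <- round(config@targetCentreDensityPerMm3 * cortexVolMm3)

  meanMap <- array(im$background[1], dims)
  sdMap <- array(im$background[2], dims)
  meanMap[medulla] <- im$medulla[1]; sdMap[medulla] <- im$medulla[2]
  meanMap[cortex] <- im$cortex[1];  sdMap[cortex] <- im$cortex[2]
  meanMap[capsule] <- im$capsule[1]; sdMap[capsule] <- im$capsule[2]

  # lognormal diameter jitter around the configured mean
  m <- config@glomerulusMeanDiameterUm
  s <- config@glomerulusDiameterSdFrac * m
  meanlog <- log(m^2 / sqrt(m^2 + s^2))
  sdlog <- sqrt(log(1 + s^2 / m^2))

  cortexIdx <- which(cortex)
  labels <- array(0L, dims)
  centres <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  placed <- 0L
  if (nTarget > 0) {
    for (g in seq_len(nTarget)) {
      ok <- FALSE
      for (attempt in seq_len(500L)) {
        v <- cortexIdx[sample.int(length(cortexIdx), 1L)]
        ijk <- arrayInd(v, dims)
        cand <- (as.numeric(ijk) - 1) * sp + stats::runif(3, -0.5, 0.5) * sp
        r <- stats::rlnorm(1, meanlog, sdlog) / 2
        vi <- round(cand / sp) + 1
        if (any(vi < 1) || any(vi > dims) || !cortex[vi[1], vi[2], vi[3]])
          next
        if (nrow(centres) > 0) {
          d <- sqrt(rowSums(sweep(centres, 2, cand, "-")^2))
          if (any(d < radii + r)) next
        }
        centres <- rbind(centres, cand)
        radii <- c(radii, r)
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok) break
    }
    if (placed == 0L)
      stop("infeasible geometry: could not place any glomerulus in the ",
           "cortical shell at the requested density")
    if (placed < nTarget)
      warning(sprintf("placed %d of %d glomeruli before saturation",
                      placed, nTarget))
    for (g in seq_len(placed)) {
      f <- fillSphere(dims, sp, centres[g, ], radii[g])
      labels <- paintRegion(labels, f, g)
      meanMap <- paintRegion(meanMap, f, im$glomerulus[1])
      sdMap <- paintRegion(sdMap, f, im$glomerulus[2])
    }
  }

  catDf <- data.frame(id = seq_len(placed),
                    x_um = if (placed) centres[, 1] else numeric(0),
                    y_um = if (placed) centres[, 2] else numeric(0),
                    z_um = if (placed) centres[, 3] else numeric(0),
                    radius_um = radii,
                    class = rep("glomerulus", placed))

  # distractors: fat blobs in the capsule rim, clots in the medulla,
  # tubule segments in the cortex
  distDf <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                     z_um = numeric(0), radius_um = numeric(0),
                     class = character(0))
  placeBlobs <- function(mask, rate, radMeanUm) {
    vol <- sum(mask) * sp^3 / 1e9
    n <- round(rate * vol)
    idx <- which(mask)
    out <- list()
    if (n > 0 && length(idx) > 0) {
      for (b in seq_len(n)) {
        for (attempt in seq_len(200L)) {
          v <- idx[sample.int(length(idx), 1L)]
          ijk <- arrayInd(v, dims)
          cand <- (as.numeric(ijk) - 1) * sp
          r <- radMeanUm * stats::runif(1, 0.8, 1.2)
          if (nrow(centres) > 0) {
            d <- sqrt(rowSums(sweep(centres, 2, cand, "-")^2))
            if (any(d < radii + r)) next
          }
          out[[length(out) + 1L]] <- c(cand, r)
          break
        }
      }
    }
    if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 4)
  }

  fat <- placeBlobs(capsule, config@distractorRates[["fat"]], 100)
  clot <- placeBlobs(medulla, config@distractorRates[["clot"]], 90)
  for (b in seq_len(nrow(fat))) {
    f <- fillSphere(dims, sp, fat[b, 1:3], fat[b, 4])
    meanMap <- paintRegion(meanMap, f, im$fat[1])
    sdMap <- paintRegion(sdMap, f, im$fat[2])
  }
  for (b in seq_len(nrow(clot))) {
    f <- fillSphere(dims, sp, clot[b, 1:3], clot[b, 4])
    meanMap <- paintRegion(meanMap, f, im$clot[1])
    sdMap <- paintRegion(sdMap, f, im$clot[2])
  }

  nTub <- round(config@distractorRates[["tubule"]] * cortexVolMm3)
  tub <- matrix(numeric(0), 0, 4)
  for (b in seq_len(nTub)) {
    for (attempt in seq_len(200L)) {
      v <- cortexIdx[sample.int(length(cortexIdx), 1L)]
      ijk <- arrayInd(v, dims)
      p0 <- (as.numeric(ijk) - 1) * sp
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- stats::runif(1, 300, 500)
      p1 <- p0 + dir * len
      rTub <- stats::runif(1, 25, 35)
      # keep tubules clear of glomeruli (check samples along the axis)
      if (nrow(centres) > 0) {
        tt <- seq(0, 1, length.out = 10)
        pts <- outer(tt, p1 - p0) + matrix(p0, 10, 3, byrow = TRUE)
        mind <- min(apply(pts, 1, function(p)
          min(sqrt(rowSums(sweep(centres, 2, p, "-")^2)) - radii)))
        if (mind < rTub + 10) next
      }
      f <- fillCylinder(dims, sp, p0, p1, rTub)
      if (is.null(f)) next
      meanMap <- paintRegion(meanMap, f, im$tubule[1])
      sdMap <- paintRegion(sdMap, f, im$tubule[2])
      tub <- rbind(tub, c((p0 + p1) / 2, rTub))
      break
    }
  }
  addDist <- function(mat, klass) {
    if (nrow(mat) == 0) return(NULL)
    data.frame(id = seq_len(nrow(mat)), x_um = mat[, 1], y_um = mat[, 2],
               z_um = mat[, 3], radius_um = mat[, 4], class = klass)
  }
  distDf <- do.call(rbind, c(list(distDf), Filter(Negate(is.null), list(
    addDist(fat, "fat"), addDist(clot, "clot"), addDist(tub, "tubule")))))
  if (nrow(distDf)) distDf$id <- seq_len(nrow(distDf))

  n <- prod(dims)
  img <- meanMap + array(stats::rnorm(n), dims) *
    sqrt(sdMap^2 + config@noiseSd^2)
  img <- round(pmin(pmax(img, 0), 65535))

  new("PhantomScene",
      image = volume3d(img, spacingUm = sp, bitDepth = 16L),
      truthLabels = labelVolume(labels, spacingUm = sp, kind = "instance"),
      regionMasks = list(cortex = cortex, medulla = medulla,
                         capsule = capsule),
      catalogue = catDf, distractors = distDf,
      transformToParent = identityTransform(), config = config)
}

#' Derive a lower-resolution copy of a phantom scene
#'
#' The parent image is Gaussian-blurred (sigma = 0.5 x factor voxels,
#' standard anti-aliasing), mapped through the child-to-parent transform and
#' block-averaged by \code{factor}; truth labels and region masks are
#' resampled nearest-neighbour; the catalogue is carried through the exact
#' inverse transform. The transform is recorded in the child scene so that
#' \code{applyTransform(transformToParent(child), childPoint)} reproduces
#' parent coordinates exactly.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param factor integer downsampling factor (>= 2).
#' @param transform \linkS4class{RigidScaleTransform} mapping child physical
#'   coordinates onto parent ones (default identity).
#' @return the child \linkS4class{PhantomScene}.
#' @export
deriveLowerResolution <- function(scene, factor, transform = identityTransform()) {
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be >= 2")
  pDims <- dim(voxels(sceneImage(scene)))
  cDims <- pDims %/% factor
  if (any(cDims < 32L))
    stop("factor reduces an axis below 32 voxels")
  sp <- spacingUm(scene)
  cSp <- sp * factor
  # child voxel (1,1,1) centre = mean of the first factor^3 parent voxel block
  cOrigin <- originUm(sceneImage(scene)) + (factor - 1) / 2 * sp
  parentToChild <- invertTransform(transform)

  blurred <- cpp_gaussian_blur(voxels(sceneImage(scene)), pDims, 0.5 * factor)
  # fine intermediate grid aligned with the child grid, parent spacing
  iDims <- cDims * factor
  iOrigin <- originUm(sceneImage(scene))
  fine <- cpp_resample_rigid(blurred, pDims,
                             originUm(sceneImage(scene)), sp,
                             iDims, iOrigin, sp,
                             parentToChild@centreFixedUm,
                             parentToChild@centreMovingUm,
                             totalThetaDeg(parentToChild),
                             parentToChild@scale,
                             parentToChild@translationUm, FALSE)
  fine[is.na(fine)] <- 0
  cImg <- cpp_block_average(fine, iDims, factor)
  cImg <- round(pmin(pmax(cImg, 0), 65535))

  nnResample <- function(arr) {
    out <- cpp_resample_rigid(array(as.numeric(arr), pDims), pDims,
                              originUm(sceneImage(scene)), sp,
                              cDims, cOrigin, cSp,
                              parentToChild@centreFixedUm,
                              parentToChild@centreMovingUm,
                              totalThetaDeg(parentToChild),
                              parentToChild@scale,
                              parentToChild@translationUm, TRUE)
    out[is.na(out)] <- 0
    out
  }
  cLab <- nnResample(labelArray(truthLabels(scene)))
  masks <- lapply(scene@regionMasks, function(m) nnResample(m) > 0.5)

  # keep only instances surviving on the child grid; relabel contiguously
  parent <- catalogue(scene)
  survived <- sort(unique(as.integer(cLab[cLab > 0])))
  keep <- parent[parent$id %in% survived, , drop = FALSE]
  newLab <- array(0L, cDims)
  newCat <- keep
  if (nrow(keep) > 0) {
    childCentres <- applyTransform(parentToChild,
                                   as.matrix(keep[, c("x_um", "y_um", "z_um")]))
    newCat$x_um <- childCentres[, 1]
    newCat$y_um <- childCentres[, 2]
    newCat$z_um <- childCentres[, 3]
    newCat$radius_um <- keep$radius_um * parentToChild@scale
    newCat$parent_id <- keep$id
    newCat$id <- seq_len(nrow(keep))
    for (r in seq_len(nrow(keep)))
      newLab[cLab == keep$id[r]] <- r
  }

  cfg <- scene@config
  cfg@volumeShape <- as.integer(cDims)
  cfg@spacingUm <- cSp

  new("PhantomScene",
      image = volume3d(array(cImg, cDims), spacingUm = cSp, bitDepth = 16L,
                       originUm = cOrigin),
      truthLabels = labelVolume(newLab, spacingUm = cSp, originUm = cOrigin,
                                kind = "instance"),
      regionMasks = masks, catalogue = newCat,
      distractors = scene@distractors,
      transformToParent = transform, config = cfg)
}
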