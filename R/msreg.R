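asGrid <- function(x) {
  if (is(x, "Volume3D"))
    list(dims = dim(voxels(x)), spacingUm = spacingUm(x),
         originUm = originUm(x))
  else if (is(x, "LabelVolume"))
    list(dims = dim(labelArray(x)), spacingUm = spacingUm(x),
         originUm = originUm(x))
  else x
}

#' Resample a moving volume onto a fixed grid under a transform
#'
#' @param moving a \linkS4class{Volume3D}.
#' @param target the fixed grid: a \linkS4class{Volume3D},
#'   \linkS4class{LabelVolume}, or list(dims, spacingUm, originUm).
#' @param transform \linkS4class{RigidScaleTransform} mapping moving
#'   physical coordinates into the fixed frame.
#' @param interp "linear" or "nearest".
#' @return array on the fixed grid; voxels outside the moving support
#'   are NA.
#' @export
resampleVolume <- function(moving, target, transform = identityTransform(),
                           interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  g <- asGrid(target)
  cpp_resample_rigid(array(as.numeric(voxels(moving)), dim(voxels(moving))),
                     dim(voxels(moving)), originUm(moving),
                     spacingUm(moving), as.integer(g$dims), g$originUm,
                     g$spacingUm, transform@centreFixedUm,
                     transform@centreMovingUm, totalThetaDeg(transform),
                     transform@scale, transform@translationUm,
                     interp == "nearest")
}

#' Mutual information between a fixed volume and a resampled moving volume
#'
#' Mutual information of the joint intensity histogram over the overlap
#' region (higher = better aligned); deterministic for full sampling. NA
#' voxels in the resampled moving volume mark missing support and are
#' excluded; at least 10 percent of the fixed volume must overlap.
#'
#' @param fixed \linkS4class{Volume3D} or numeric array.
#' @param movingResampled array on the fixed grid (NA outside support).
#' @param bins histogram bins per side (default 50).
#' @return mutual information in nats.
#' @export
mattesMI <- function(fixed, movingResampled, bins = 50L) {
  fx <- if (is(fixed, "Volume3D")) voxels(fixed) else fixed
  mv <- if (is(movingResampled, "Volume3D")) voxels(movingResampled)
        else movingResampled
  if (!identical(dim(fx), dim(mv))) stop("grids differ")
  mask <- !is.na(mv)
  if (mean(mask) < 0.10)
    stop("insufficient overlap between fixed and moving volumes")
  a <- as.numeric(fx[mask])
  b <- as.numeric(mv[mask])
  # Parzen-windowed (linear-kernel) joint histogram over continuous bin
  # coordinates: smooth in the intensities, so the metric surface is free
  # of hard-binning artifacts during pose optimisation
  binPos <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(0, length(x)))
    (x - r[1]) / (r[2] - r[1]) * (bins - 1)
  }
  h <- cpp_joint_hist_parzen(binPos(a), binPos(b), bins)
  p <- h / sum(h)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# resolution-match the moving volume to the fixed grid before metric
# evaluation: Gaussian blur at sigma = 0.5 x spacing ratio (the standard
# anti-aliasing width), then block-average so the moving spacing stays
# within 2x of the fixed spacing. Avoids aliasing in the joint histogram
# and centres the metric optimum on the true pose.
prebinMoving <- function(moving, fixedSpacingUm) {
  ratio <- fixedSpacingUm / spacingUm(moving)
  if (ratio <= 1) return(moving)
  arr <- array(as.numeric(voxels(moving)), dim(voxels(moving)))
  # anti-aliasing plus the half-fixed-voxel smoothing applied to the fixed
  # side during registration, composed in moving-voxel units
  arr <- cpp_gaussian_blur(arr, dim(arr), 0.5 * sqrt(ratio^2 + 1))
  f <- max(1L, as.integer(floor(ratio / 2)))
  org <- originUm(moving)
  sp <- spacingUm(moving)
  if (f > 1L) {
    arr <- cpp_block_average(arr, dim(arr), f)
    org <- org + (f - 1) / 2 * sp
    sp <- sp * f
  }
  volume3d(arr, spacingUm = sp, bitDepth = 0L, originUm = org)
}

miAtPose <- function(fixed, moving, fixedPointUm, movingPointUm, thetaDeg,
                     scale, bins) {
  t <- rigidScaleTransform(centreFixedUm = fixedPointUm,
                           centreMovingUm = movingPointUm,
                           thetaZDeg = thetaDeg, scale = scale)
  mattesMI(fixed, resampleVolume(moving, fixed, t), bins = bins)
}

#' Coarse exhaustive z-rotation search
#'
#' Evaluates mutual information on a full 360-degree sweep about the fixed
#' common point (step 2 degrees: 180 poses) and returns the best angle.
#'
#' @param fixed,moving \linkS4class{Volume3D}s.
#' @param fixedPointUm,movingPointUm the manually selected common point in
#'   each frame (um).
#' @param stepDeg sweep step (default 2).
#' @param rangeDeg sweep extent (default 360).
#' @param scale nominal scale during the sweep (default 1; physical
#'   coordinates already account for voxel spacing).
#' @param bins MI histogram bins.
#' @return list with \code{bestAngle} and \code{trace}
#'   (data.frame angle, mi).
#' @export
coarseZSearch <- function(fixed, moving, fixedPointUm, movingPointUm,
                          stepDeg = 2, rangeDeg = 360, scale = 1,
                          bins = 50L) {
  angles <- seq(0, rangeDeg - stepDeg, by = stepDeg)
  mi <- vapply(angles, function(a)
    miAtPose(fixed, moving, fixedPointUm, movingPointUm, a, scale, bins),
    numeric(1))
  list(bestAngle = angles[which.max(mi)],
       trace = data.frame(angle = angles, mi = mi))
}

#' Fine exhaustive z-rotation search
#'
#' Sweeps a 5-degree window (interpreted as +/- 2.5 degrees around the
#' coarse optimum, covering the adjacent 2-degree coarse bins) at 0.1
#' degree steps.
#'
#' @inheritParams coarseZSearch
#' @param centreAngle the coarse-stage optimum (degrees).
#' @param windowDeg total window width (default 5).
#' @param stepDeg sweep step (default 0.1).
#' @return list with \code{bestAngle} and \code{trace}.
#' @export
refineZSearch <- function(fixed, moving, fixedPointUm, movingPointUm,
                          centreAngle, windowDeg = 5, stepDeg = 0.1,
                          scale = 1, bins = 50L) {
  angles <- centreAngle + seq(-windowDeg / 2, windowDeg / 2, by = stepDeg)
  mi <- vapply(angles, function(a)
    miAtPose(fixed, moving, fixedPointUm, movingPointUm, a, scale, bins),
    numeric(1))
  list(bestAngle = angles[which.max(mi)],
       trace = data.frame(angle = angles, mi = mi))
}

#' Bounded quasi-Newton refinement of in-plane rotation and scale
#'
#' Maximises mutual information over the secondary in-plane angle and the
#' isotropic scale with L-BFGS-B (the z-rotation from the staged searches
#' stays fixed). The scale is seeded by a short grid sweep before the
#' quasi-Newton stage. Bounds default to +/-10 degrees and [0.8, 1.25]
#' around the nominal spacing ratio. If the optimiser ends below the
#' initial metric the initial transform is returned with a warning.
#'
#' @param fixed,moving \linkS4class{Volume3D}s.
#' @param init \linkS4class{RigidScaleTransform} from the z-search stages.
#' @param maxIter iteration cap (default 2000).
#' @param thetaXYBounds bounds on the secondary angle (degrees).
#' @param scaleBounds bounds on the scale factor.
#' @param bins MI histogram bins.
#' @return list with \code{transform}, \code{trace} (data.frame thetaXY,
#'   scale, mi per evaluation), \code{initMI}, \code{finalMI}.
#' @export
optimisePose <- function(fixed, moving, init, maxIter = 2000L,
                         thetaXYBounds = c(-10, 10),
                         scaleBounds = c(0.8, 1.25), bins = 50L) {
  evalLog <- new.env()
  evalLog$rows <- list()
  obj <- function(par) {
    t <- rigidScaleTransform(centreFixedUm = init@centreFixedUm,
                             centreMovingUm = init@centreMovingUm,
                             thetaZDeg = init@thetaZDeg,
                             thetaXYDeg = par[1], scale = par[2],
                             translationUm = init@translationUm)
    mi <- tryCatch(mattesMI(fixed, resampleVolume(moving, fixed, t), bins),
                   error = function(e) -Inf)
    evalLog$rows[[length(evalLog$rows) + 1L]] <-
      data.frame(thetaXY = par[1], scale = par[2], mi = mi)
    mi
  }
  initMI <- obj(c(init@thetaXYDeg, init@scale))

  # seed the quasi-Newton stage: MI is much flatter in scale than in angle
  # and locally stepped in both, so short grid sweeps give the
  # finite-difference gradients a good starting point
  scaleSweep <- seq(max(scaleBounds[1], 0.9), min(scaleBounds[2], 1.1), by = 0.02)
  sweepMI <- vapply(scaleSweep, function(s) obj(c(init@thetaXYDeg, s)), numeric(1))
  s0 <- scaleSweep[which.max(sweepMI)]
  thSweep <- init@thetaXYDeg + seq(-0.75, 0.75, by = 0.05)
  thMI <- vapply(thSweep, function(th) obj(c(th, s0)), numeric(1))
  th0 <- thSweep[which.max(thMI)]

  fit <- stats::optim(c(th0, s0), obj, method = "L-BFGS-B",
                      lower = c(thetaXYBounds[1], scaleBounds[1]),
                      upper = c(thetaXYBounds[2], scaleBounds[2]),
                      control = list(fnscale = -1, maxit = maxIter,
                                     ndeps = c(0.02, 0.002)))
  # deterministic coordinate polish with shrinking steps: the
  # finite-difference quasi-Newton stage can stall within a step of the
  # optimum on a shallow metric surface
  par <- fit$par
  val <- fit$value
  for (step in list(c(0.1, 0.002), c(0.05, 0.001), c(0.025, 0.0005))) {
    improved <- TRUE
    iter <- 0L
    while (improved && iter < 20L) {
      improved <- FALSE
      iter <- iter + 1L
      for (d in list(c(step[1], 0), c(-step[1], 0),
                     c(0, step[2]), c(0, -step[2]))) {
        cand <- pmin(pmax(par + d, c(thetaXYBounds[1], scaleBounds[1])),
                     c(thetaXYBounds[2], scaleBounds[2]))
        v <- obj(cand)
        if (v > val + 1e-12) {
          par <- cand
          val <- v
          improved <- TRUE
        }
      }
    }
  }
  fit$par <- par
  fit$value <- val
  finalMI <- fit$value
  out <- init
  if (finalMI < initMI - 1e-9) {
    warning("pose optimisation ended below the initial metric; ",
            "returning the initial transform")
    finalMI <- initMI
  } else {
    out@thetaXYDeg <- fit$par[1]
    out@scale <- fit$par[2]
  }
  list(transform = out, trace = do.call(rbind, evalLog$rows),
       initMI = initMI, finalMI = finalMI)
}

#' Full staged registration of a moving volume into a fixed volume
#'
#' Runs the coarse 2-degree full-circle z-rotation sweep, the 0.1-degree
#' fine sweep over a 5-degree window, and the bounded quasi-Newton
#' refinement of in-plane rotation and scale, all about a pair of manually
#' selected common points. Translation beyond the common-point alignment is
#' fixed at zero. The moving volume is block-averaged to within 2x of the
#' fixed spacing before metric evaluation.
#'
#' @param fixed lower-resolution fixed \linkS4class{Volume3D}.
#' @param moving higher-resolution moving \linkS4class{Volume3D}.
#' @param fixedPointUm,movingPointUm corresponding common points (um).
#' @param bins MI histogram bins (default 50).
#' @param maxIter L-BFGS-B iteration cap (default 2000).
#' @return list with \code{transform} (moving -> fixed), \code{trace}
#'   (coarse/refined/optimiser stages; stage-best MI is non-decreasing) and
#'   \code{finalMI}.
#' @export
registerVolumes <- function(fixed, moving, fixedPointUm, movingPointUm,
                            bins = 50L, maxIter = 2000L) {
  mv <- prebinMoving(moving, spacingUm(fixed))
  # a half-voxel blur of the fixed volume suppresses the angular
  # interpolation artifacts of the joint histogram (the moving side gets
  # the matching smoothing in prebinMoving)
  fxArr <- cpp_gaussian_blur(array(as.numeric(voxels(fixed)),
                                   dim(voxels(fixed))),
                             dim(voxels(fixed)), 0.5)
  fx <- volume3d(fxArr, spacingUm = spacingUm(fixed), bitDepth = 0L,
                 originUm = originUm(fixed))
  coarse <- coarseZSearch(fx, mv, fixedPointUm, movingPointUm,
                          bins = bins)
  refined <- refineZSearch(fx, mv, fixedPointUm, movingPointUm,
                           coarse$bestAngle, bins = bins)
  init <- rigidScaleTransform(centreFixedUm = fixedPointUm,
                              centreMovingUm = movingPointUm,
                              thetaZDeg = refined$bestAngle, scale = 1)
  opt <- optimisePose(fx, mv, init, maxIter = maxIter, bins = bins)
  list(transform = opt$transform,
       trace = list(coarse = coarse$trace, refined = refined$trace,
                    optimiser = opt$trace),
       finalMI = opt$finalMI)
}

#' Resample labels through a transform as pseudo-labels
#'
#' Nearest-neighbour interpolation preserves instance IDs exactly; target
#' voxels outside the source support become background (0). The number of
#' distinct IDs can only decrease.
#'
#' @param labels a \linkS4class{LabelVolume} in the moving frame.
#' @param transform \linkS4class{RigidScaleTransform} mapping moving
#'   physical coordinates into the fixed frame.
#' @param target the fixed grid (\linkS4class{Volume3D},
#'   \linkS4class{LabelVolume} or list(dims, spacingUm, originUm)).
#' @return a \linkS4class{LabelVolume} on the fixed grid, with a logical
#'   \code{support} attribute marking where the moving volume had support.
#' @export
resampleLabels <- function(labels, transform, target) {
  g <- asGrid(target)
  out <- cpp_resample_rigid(array(as.numeric(labelArray(labels)),
                                  dim(labelArray(labels))),
                            dim(labelArray(labels)), originUm(labels),
                            spacingUm(labels), as.integer(g$dims),
                            g$originUm, g$spacingUm,
                            transform@centreFixedUm,
                            transform@centreMovingUm,
                            totalThetaDeg(transform), transform@scale,
                            transform@translationUm, TRUE)
  support <- !is.na(out)
  out[!support] <- 0
  lv <- labelVolume(array(as.integer(out), g$dims), spacingUm = g$spacingUm,
                    originUm = g$originUm, kind = labelKind(labels))
  attr(lv, "support") <- support
  lv
}

#' Tile a registered prediction into pseudo-labelled training cubes
#'
#' Tiles the corner-aligned registered overlap region into disjoint cubes
#' and attaches pseudo provenance. Each cube's labels equal the
#' corresponding crop of the resampled prediction exactly.
#'
#' @param lowresImage the fixed-frame \linkS4class{Volume3D}.
#' @param resampledPred \linkS4class{LabelVolume} from
#'   \code{\link{resampleLabels}} on the same grid.
#' @param cubeEdge cube edge in voxels (default 128).
#' @param supportMask optional logical array restricting tiling to the
#'   registered overlap (defaults to the prediction's support attribute,
#'   else the full grid).
#' @param sampleId sample identifier for the cubes.
#' @param resolutionLevel level tag for the cubes.
#' @return list of \linkS4class{AnnotatedCube} with provenance "pseudo".
#' @export
makePseudoCubes <- function(lowresImage, resampledPred, cubeEdge = 128L,
                            supportMask = NULL, sampleId = "sample",
                            resolutionLevel = "low") {
  cubeEdge <- as.integer(cubeEdge)
  d <- dim(voxels(lowresImage))
  if (!identical(d, dim(labelArray(resampledPred))))
    stop("image and prediction grids differ")
  if (is.null(supportMask))
    supportMask <- attr(resampledPred, "support")
  if (is.null(supportMask)) supportMask <- array(TRUE, d)
  idx <- which(supportMask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("registered overlap smaller than one cube")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  ext <- hi - lo + 1L
  if (any(ext < cubeEdge))
    stop("registered overlap smaller than one cube")
  nper <- ext %/% cubeEdge
  sp <- spacingUm(lowresImage)
  org <- originUm(lowresImage)
  img <- voxels(lowresImage)
  lab <- labelArray(resampledPred)
  out <- list()
  m <- 0L
  for (k in seq_len(nper[3])) for (j in seq_len(nper[2]))
    for (i in seq_len(nper[1])) {
      corner <- lo + (c(i, j, k) - 1L) * cubeEdge - 1L
      rx <- corner[1] + seq_len(cubeEdge)
      ry <- corner[2] + seq_len(cubeEdge)
      rz <- corner[3] + seq_len(cubeEdge)
      pOrg <- org + corner * sp
      m <- m + 1L
      out[[m]] <- annotatedCube(
        volume3d(img[rx, ry, rz, drop = FALSE], spacingUm = sp,
                 bitDepth = bitDepth(lowresImage), originUm = pOrg),
        labelVolume(lab[rx, ry, rz, drop = FALSE], spacingUm = sp,
                    originUm = pOrg, kind = labelKind(resampledPred)),
        sampleId = sampleId, cubeId = sprintf("pseudo-%03d", m),
        resolutionLevel = resolutionLevel, provenance = "pseudo")
    }
  out
}
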