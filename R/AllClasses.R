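#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib glomscale, .registration = TRUE
NULL

#' Volume3D: a 3D intensity grid with isotropic voxel spacing
#'
#' The unit of all image I/O in the package. Voxel centres sit at
#' \code{originUm + (index - 1) * spacingUm} in physical micrometre
#' coordinates, per axis, with R's column-major array layout.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacingUm isotropic voxel spacing in micrometres (scalar, > 0).
#' @slot bitDepth 8L or 16L for integer-range data, 0L for unconstrained
#'   floating-point data (e.g. probability maps).
#' @slot originUm physical coordinate (um) of the centre of voxel (1,1,1).
#' @export
setClass("Volume3D",
  representation(voxels = "array", spacingUm = "numeric",
                 bitDepth = "integer", originUm = "numeric"),
  prototype(spacingUm = 1, bitDepth = 16L, originUm = c(0, 0, 0)))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacingUm) != 1L || !is.finite(object@spacingUm) ||
      object@spacingUm <= 0)
    msg <- c(msg, "spacingUm must be a positive scalar")
  if (!object@bitDepth %in% c(0L, 8L, 16L))
    msg <- c(msg, "bitDepth must be 0 (float), 8 or 16")
  if (length(object@originUm) != 3L)
    msg <- c(msg, "originUm must be a 3-vector")
  if (object@bitDepth > 0L) {
    rng <- suppressWarnings(range(object@voxels, na.rm = TRUE))
    if (is.finite(rng[1]) &&
        (rng[1] < 0 || rng[2] > 2^object@bitDepth - 1))
      msg <- c(msg, "intensities outside bit-depth range")
  }
  if (length(msg)) msg else TRUE
})

#' LabelVolume: a label grid aligned voxel-for-voxel to a Volume3D
#'
#' @slot labels 3D integer-valued array; background is 0.
#' @slot spacingUm voxel spacing in micrometres.
#' @slot originUm physical origin (um) of voxel (1,1,1).
#' @slot kind "binary" (0/1) or "instance" (0 background, IDs 1..K).
#' @export
setClass("LabelVolume",
  representation(labels = "array", spacingUm = "numeric",
                 originUm = "numeric", kind = "character"),
  prototype(spacingUm = 1, originUm = c(0, 0, 0), kind = "binary"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!object@kind %in% c("binary", "instance"))
    msg <- c(msg, "kind must be 'binary' or 'instance'")
  if (any(object@labels < 0, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative")
  if (object@kind == "binary" && any(object@labels > 1, na.rm = TRUE))
    msg <- c(msg, "binary labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' RigidScaleTransform: fixed-centre rigid + isotropic scale map
#'
#' Maps moving-frame physical coordinates (um) to fixed-frame ones:
#' \deqn{x_f = c_f + R_z(\theta_z + \theta_{xy}) \, s \, (x_m - c_m) + t}
#' where \eqn{R_z} rotates in the xy-plane about the z axis. The coarse/fine
#' exhaustive search fills \code{thetaZDeg}; the quasi-Newton refinement
#' adjusts the secondary in-plane angle \code{thetaXYDeg} and \code{scale}.
#'
#' @slot centreFixedUm fixed-frame common point (um).
#' @slot centreMovingUm moving-frame common point (um).
#' @slot thetaZDeg primary rotation about z, degrees.
#' @slot thetaXYDeg secondary in-plane rotation, degrees.
#' @slot scale isotropic scale factor (> 0).
#' @slot translationUm residual translation (um), fixed frame.
#' @export
setClass("RigidScaleTransform",
  representation(centreFixedUm = "numeric", centreMovingUm = "numeric",
                 thetaZDeg = "numeric", thetaXYDeg = "numeric",
                 scale = "numeric", translationUm = "numeric"),
  prototype(centreFixedUm = c(0, 0, 0), centreMovingUm = c(0, 0, 0),
            thetaZDeg = 0, thetaXYDeg = 0, scale = 1,
            translationUm = c(0, 0, 0)))

setValidity("RigidScaleTransform", function(object) {
  msg <- character()
  if (length(object@centreFixedUm) != 3L || length(object@centreMovingUm) != 3L ||
      length(object@translationUm) != 3L)
    msg <- c(msg, "centres and translation must be 3-vectors")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "scale must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' PhantomConfig: parameters of the synthetic multiscale kidney phantom
#'
#' Defaults follow the statistical structure of high-resolution HiP-CT kidney
#' data: glomeruli as bright quasi-spheres of ~200 um mean diameter placed at
#' a mean centre density of 9.4 per mm^3 of cortex, inside an ellipsoidal
#' cortical shell, with fat, clot and tubule distractor structures.
#'
#' @slot volumeShape voxels per axis (3 integers).
#' @slot spacingUm micrometres per voxel (isotropic).
#' @slot glomerulusMeanDiameterUm mean glomerular diameter (um).
#' @slot glomerulusDiameterSdFrac lognormal diameter jitter as a fraction of
#'   the mean (default 0.15).
#' @slot targetCentreDensityPerMm3 glomerular centre density per mm^3 cortex.
#' @slot cortexInnerRadiiUm,cortexOuterRadiiUm semi-axes (um) of the inner
#'   (medullary) and outer ellipsoids delimiting the cortical shell.
#' @slot capsuleThicknessUm thickness of the perirenal fat/capsule rim (um).
#' @slot distractorRates named numeric: fat blobs, clot blobs and tubule
#'   segments per mm^3 of their host region (capsule, medulla, cortex).
#' @slot intensityModel named list of c(mean, sd) 16-bit intensities per
#'   tissue class.
#' @slot noiseSd additive Gaussian image noise (16-bit units).
#' @slot seed integer RNG seed; identical (config, seed) pairs give
#'   bit-identical phantoms.
#' @export
setClass("PhantomConfig",
  representation(volumeShape = "integer", spacingUm = "numeric",
                 glomerulusMeanDiameterUm = "numeric",
                 glomerulusDiameterSdFrac = "numeric",
                 targetCentreDensityPerMm3 = "numeric",
                 cortexInnerRadiiUm = "numeric",
                 cortexOuterRadiiUm = "numeric",
                 capsuleThicknessUm = "numeric",
                 distractorRates = "numeric",
                 intensityModel = "list",
                 noiseSd = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 8L))
    msg <- c(msg, "volumeShape must be 3 integers >= 8")
  if (object@spacingUm <= 0) msg <- c(msg, "spacingUm must be positive")
  if (object@glomerulusMeanDiameterUm <= 0)
    msg <- c(msg, "glomerulus diameter must be positive")
  if (object@targetCentreDensityPerMm3 < 0)
    msg <- c(msg, "density must be non-negative")
  if (any(object@cortexInnerRadiiUm <= 0) || any(object@cortexOuterRadiiUm <= 0))
    msg <- c(msg, "cortex radii must be positive")
  if (any(object@cortexInnerRadiiUm >= object@cortexOuterRadiiUm))
    msg <- c(msg, "cortex inner radii must be < outer radii")
  need <- c("fat", "clot", "tubule")
  if (!all(need %in% names(object@distractorRates)))
    msg <- c(msg, "distractorRates must name fat, clot, tubule")
  if (length(msg)) msg else TRUE
})

#' PhantomScene: a rendered phantom with complete ground truth
#'
#' @slot image rendered \linkS4class{Volume3D}.
#' @slot truthLabels glomerulus instance \linkS4class{LabelVolume}.
#' @slot regionMasks list of logical arrays: cortex, medulla, capsule.
#' @slot catalogue data.frame (id, x_um, y_um, z_um, radius_um, class) of
#'   glomeruli; IDs are contiguous from 1 and every instance has voxels in
#'   \code{truthLabels}.
#' @slot distractors data.frame of distractor structures (same columns).
#' @slot transformToParent \linkS4class{RigidScaleTransform} mapping this
#'   scene's physical coordinates onto its parent's (identity for a root
#'   scene).
#' @slot config the generating \linkS4class{PhantomConfig}.
#' @export
setClass("PhantomScene",
  representation(image = "Volume3D", truthLabels = "LabelVolume",
                 regionMasks = "list", catalogue = "data.frame",
                 distractors = "data.frame",
                 transformToParent = "RigidScaleTransform",
                 config = "PhantomConfig"))

#' AnnotatedCube: an annotated training cube at one resolution level
#'
#' @slot image \linkS4class{Volume3D} cube.
#' @slot labels matching \linkS4class{LabelVolume}.
#' @slot sampleId character id of the originating sample/organ.
#' @slot cubeId character id unique within the sample.
#' @slot resolutionLevel "high", "intermediate" or "low".
#' @slot provenance "manual" or "pseudo".
#' @export
setClass("AnnotatedCube",
  representation(image = "Volume3D", labels = "LabelVolume",
                 sampleId = "character", cubeId = "character",
                 resolutionLevel = "character", provenance = "character"),
  prototype(sampleId = "sample", cubeId = "cube",
            resolutionLevel = "high", provenance = "manual"))

setValidity("AnnotatedCube", function(object) {
  msg <- character()
  if (!identical(dim(object@image@voxels), dim(object@labels@labels)))
    msg <- c(msg, "image and labels must share a grid")
  if (!object@resolutionLevel %in% c("high", "intermediate", "low"))
    msg <- c(msg, "resolutionLevel must be high/intermediate/low")
  if (!object@provenance %in% c("manual", "pseudo"))
    msg <- c(msg, "provenance must be manual/pseudo")
  if (length(msg)) msg else TRUE
})

#' Patch: a training patch cut from an AnnotatedCube
#'
#' @slot image \linkS4class{Volume3D} patch.
#' @slot labels matching \linkS4class{LabelVolume}.
#' @slot parentCubeId id of the source cube.
#' @slot cornerIndex 0-based voxel offset of the patch corner in the cube.
#' @export
setClass("Patch",
  representation(image = "Volume3D", labels = "LabelVolume",
                 parentCubeId = "character", cornerIndex = "integer"))

#' ThresholdSet: one candidate instance false-positive filter
#'
#' Unset criteria are NA and inactive. The radius floor defaults to 62 um
#' (the minimum credible glomerular radius after shrinkage, volume 1e6 um^3).
#'
#' @slot varianceLower,varianceUpper bounds on per-instance intensity
#'   variance (NA = inactive).
#' @slot roundnessMin minimum sphericity (NA = inactive).
#' @slot radiusMinUm minimum equivalent radius in um (default 62).
#' @slot densityWindowW neighbourhood window edge in voxels (NA = inactive).
#' @slot densityMinCount minimum centroid count D within the window,
#'   self included (NA = inactive).
#' @slot useCortexMask logical; require centroids inside the cortex mask.
#' @export
setClass("ThresholdSet",
  representation(varianceLower = "numeric", varianceUpper = "numeric",
                 roundnessMin = "numeric", radiusMinUm = "numeric",
                 densityWindowW = "numeric", densityMinCount = "numeric",
                 useCortexMask = "logical"),
  prototype(varianceLower = NA_real_, varianceUpper = NA_real_,
            roundnessMin = NA_real_, radiusMinUm = 62,
            densityWindowW = NA_real_, densityMinCount = NA_real_,
            useCortexMask = FALSE))

setValidity("ThresholdSet", function(object) {
  msg <- character()
  if (!is.na(object@varianceLower) && !is.na(object@varianceUpper) &&
      object@varianceLower >= object@varianceUpper)
    msg <- c(msg, "varianceLower must be < varianceUpper when both set")
  if (length(msg)) msg else TRUE
})

#' EmaTracker: exponential moving average of validation Dice
#'
#' First update sets the tracked value to the raw value; afterwards
#' \code{current <- alpha * current + (1 - alpha) * new}.
#'
#' @slot alpha smoothing factor (default 0.9).
#' @slot current current EMA value; length 0 before the first update.
#' @export
setClass("EmaTracker",
  representation(alpha = "numeric", current = "numeric"),
  prototype(alpha = 0.9, current = numeric(0)))

#' ZonalPartition: tripartite cortical zonation masks
#'
#' @slot inner,middle,outer disjoint logical arrays partitioning the cortex.
#' @slot bandWidthUm the band width, three mean glomerular diameters (um).
#' @slot spacingUm voxel spacing (um).
#' @export
setClass("ZonalPartition",
  representation(inner = "array", middle = "array", outer = "array",
                 bandWidthUm = "numeric", spacingUm = "numeric"))

setValidity("ZonalPartition", function(object) {
  msg <- character()
  if (any(object@inner & object@middle) || any(object@inner & object@outer) ||
      any(object@middle & object@outer))
    msg <- c(msg, "zones must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})
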