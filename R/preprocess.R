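#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Intensities are first linearly rescaled to the full bit range, then
#' slice-wise 2D CLAHE is applied along z (isotropic volumes; the
#' equalisation context is local either way). The clip limit is expressed
#' as a fraction of the per-tile histogram mass, converted to the
#' bin-relative limit used by \code{EBImage::clahe}.
#'
#' @param v a \linkS4class{Volume3D}.
#' @param clipLimit clip limit as a fraction of tile mass (default 0.01).
#' @param tileGrid number of tiles per image side (default 8).
#' @param bins histogram bins (default 256).
#' @return a \linkS4class{Volume3D} with locally equalised contrast spanning
#'   the full bit range.
#' @examples
#' v <- volume3d(array(runif(16^3, 100, 400), c(16, 16, 16)))
#' out <- applyClahe(v, tileGrid = 2)
#' @export
applyClahe <- function(v, clipLimit = 0.01, tileGrid = 8, bins = 256) {
  arr <- voxels(v)
  rng <- range(arr)
  if (rng[1] == rng[2]) {
    warning("constant volume: CLAHE undefined, returning input unchanged")
    return(v)
  }
  depth <- if (bitDepth(v) > 0) bitDepth(v) else 16L
  top <- 2^depth - 1
  norm <- (arr - rng[1]) / (rng[2] - rng[1])
  limit <- clipLimit * bins
  out <- array(0, dim(arr))
  for (k in seq_len(dim(arr)[3])) {
    out[, , k] <- as.numeric(EBImage::clahe(
      EBImage::Image(norm[, , k]), nx = tileGrid, ny = tileGrid,
      bins = bins, limit = limit))
  }
  out <- pmin(pmax(out, 0), 1) * top
  volume3d(round(out), spacingUm = spacingUm(v), bitDepth = depth,
           originUm = originUm(v))
}

#' Convert a 16-bit volume to 8-bit
#'
#' Linear min-max rescale to [0, 255] with round-half-even. A constant
#' volume maps to all zeros.
#'
#' @param v a 16-bit \linkS4class{Volume3D}.
#' @return an 8-bit \linkS4class{Volume3D}. Intensity order is preserved.
#' @examples
#' v <- volume3d(array(c(0, 32768, 65535), c(3, 1, 1)), bitDepth = 16)
#' range(voxels(toUint8(v)))
#' @export
toUint8 <- function(v) {
  if (bitDepth(v) == 8L) {
    warning("volume is already 8-bit; returning unchanged")
    return(v)
  }
  arr <- voxels(v)
  rng <- range(arr)
  out <- if (rng[1] == rng[2]) array(0, dim(arr))
         else round((arr - rng[1]) / (rng[2] - rng[1]) * 255)
  volume3d(out, spacingUm = spacingUm(v), bitDepth = 8L,
           originUm = originUm(v))
}

#' Construct an AnnotatedCube
#'
#' @param image \linkS4class{Volume3D}.
#' @param labels \linkS4class{LabelVolume} on the same grid.
#' @param sampleId,cubeId identifiers.
#' @param resolutionLevel "high", "intermediate" or "low".
#' @param provenance "manual" or "pseudo".
#' @return an \linkS4class{AnnotatedCube}.
#' @export
annotatedCube <- function(image, labels, sampleId = "sample",
                          cubeId = "cube", resolutionLevel = "high",
                          provenance = "manual") {
  new("AnnotatedCube", image = image, labels = labels, sampleId = sampleId,
      cubeId = cubeId, resolutionLevel = resolutionLevel,
      provenance = provenance)
}

#' Cut an annotated cube into non-overlapping training patches
#'
#' Tiles the cube exhaustively with corner-aligned, disjoint patches of
#' edge \code{patchEdge}; if an edge is not a multiple of \code{patchEdge}
#' the cube is corner-cropped to the largest multiple (no intensities are
#' fabricated by padding). Labels are cropped congruently.
#'
#' @param cube an \linkS4class{AnnotatedCube}.
#' @param patchEdge patch edge length in voxels (default 128).
#' @return list of \linkS4class{Patch} objects.
#' @examples
#' # a 512^3 cube yields (512/128)^3 = 64 patches
#' @export
extractPatches <- function(cube, patchEdge = 128L) {
  patchEdge <- as.integer(patchEdge)
  d <- dim(voxels(cube@image))
  if (any(patchEdge > d)) stop("patchEdge exceeds cube edge")
  nper <- d %/% patchEdge
  img <- voxels(cube@image)
  lab <- labelArray(cube@labels)
  sp <- spacingUm(cube@image)
  org <- originUm(cube@image)
  out <- vector("list", prod(nper))
  m <- 0L
  for (k in seq_len(nper[3])) for (j in seq_len(nper[2]))
    for (i in seq_len(nper[1])) {
      corner <- (c(i, j, k) - 1L) * patchEdge
      rx <- corner[1] + seq_len(patchEdge)
      ry <- corner[2] + seq_len(patchEdge)
      rz <- corner[3] + seq_len(patchEdge)
      pOrg <- org + corner * sp
      m <- m + 1L
      out[[m]] <- new("Patch",
        image = volume3d(img[rx, ry, rz, drop = FALSE], spacingUm = sp,
                         bitDepth = bitDepth(cube@image), originUm = pOrg),
        labels = labelVolume(lab[rx, ry, rz, drop = FALSE], spacingUm = sp,
                             originUm = pOrg, kind = labelKind(cube@labels)),
        parentCubeId = cube@cubeId, cornerIndex = as.integer(corner))
    }
  out
}

#' Split annotated cubes into train and test sets per sample
#'
#' Follows a global 9:1 target ratio while guaranteeing at least one test
#' cube from every sample: the per-sample test count is
#' \code{max(1, round(testFraction * n_sample))}. Deterministic under the
#' seed. A sample with a single cube is refused (its only cube would leave
#' an empty training set).
#'
#' @param cubes list of \linkS4class{AnnotatedCube}.
#' @param testFraction target test fraction (default 0.1).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test} (lists of cubes)
#'   forming a partition of the input.
#' @examples
#' # 40 cubes over samples sized (20, 7, 9, 4) give per-sample test
#' # counts (2, 1, 1, 1): 5 test, 35 train.
#' @export
splitDataset <- function(cubes, testFraction = 0.1, seed = 1L) {
  if (length(cubes) == 0) stop("empty cube list")
  samples <- vapply(cubes, function(cb) cb@sampleId, character(1))
  tab <- table(samples)
  if (any(tab < 2))
    stop("every sample needs >= 2 cubes (one test cube would leave no ",
         "training data for sample ", names(tab)[which(tab < 2)[1]], ")")
  set.seed(seed)
  testIdx <- integer(0)
  for (s in names(tab)) {
    idx <- which(samples == s)
    nTest <- max(1L, round(testFraction * length(idx)))
    testIdx <- c(testIdx, sample(idx, nTest))
  }
  list(train = cubes[setdiff(seq_along(cubes), testIdx)],
       test = cubes[sort(testIdx)])
}

#' Write a train/test split manifest as JSON
#'
#' @param split result of \code{\link{splitDataset}}.
#' @param path JSON file path; maps each cube id to "train" or "test".
#' @export
writeSplitManifest <- function(split, path) {
  ids <- function(x, tag) {
    out <- rep(tag, length(x))
    names(out) <- vapply(x, function(cb) cb@cubeId, character(1))
    out
  }
  jsonlite::write_json(as.list(c(ids(split$train, "train"),
                                 ids(split$test, "test"))),
                       path, auto_unbox = TRUE)
  invisible(path)
}
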