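#' Construct a Volume3D
#'
#' @param voxels 3D numeric array.
#' @param spacingUm isotropic voxel spacing, micrometres.
#' @param bitDepth 8, 16, or 0 for floating-point data.
#' @param originUm physical coordinate (um) of voxel (1,1,1).
#' @return a \linkS4class{Volume3D}.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 8)), spacingUm = 5)
#' spacingUm(v)
#' @export
volume3d <- function(voxels, spacingUm = 1, bitDepth = 16L,
                     originUm = c(0, 0, 0)) {
  new("Volume3D", voxels = voxels, spacingUm = as.numeric(spacingUm),
      bitDepth = as.integer(bitDepth), originUm = as.numeric(originUm))
}

#' Construct a LabelVolume
#'
#' @param labels 3D integer-valued array, background 0.
#' @param spacingUm voxel spacing, micrometres.
#' @param originUm physical origin (um).
#' @param kind "binary" or "instance".
#' @return a \linkS4class{LabelVolume}.
#' @export
labelVolume <- function(labels, spacingUm = 1, originUm = c(0, 0, 0),
                        kind = c("binary", "instance")) {
  kind <- match.arg(kind)
  new("LabelVolume", labels = labels, spacingUm = as.numeric(spacingUm),
      originUm = as.numeric(originUm), kind = kind)
}

#' @rdname accessors
#' @export
setMethod("voxels", "Volume3D", function(object, ...) object@voxels)

#' @rdname accessors
#' @export
setMethod("spacingUm", "Volume3D", function(object, ...) object@spacingUm)

#' @rdname accessors
#' @export
setMethod("spacingUm", "LabelVolume", function(object, ...) object@spacingUm)

#' @rdname accessors
#' @export
setMethod("originUm", "Volume3D", function(object, ...) object@originUm)

#' @rdname accessors
#' @export
setMethod("originUm", "LabelVolume", function(object, ...) object@originUm)

#' @rdname accessors
#' @export
setMethod("bitDepth", "Volume3D", function(object, ...) object@bitDepth)

#' @rdname accessors
#' @export
setMethod("labelArray", "LabelVolume", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setMethod("labelKind", "LabelVolume", function(object, ...) object@kind)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume3D %d x %d x %d, %.3g um/voxel, %s\n", d[1], d[2], d[3],
              object@spacingUm,
              if (object@bitDepth > 0) paste0(object@bitDepth, "-bit")
              else "float"))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume (%s) %d x %d x %d, %.3g um/voxel, %d foreground voxels\n",
              object@kind, d[1], d[2], d[3], object@spacingUm,
              sum(object@labels > 0)))
})

#' Physical coordinates of voxel indices
#'
#' @param v a \linkS4class{Volume3D} or \linkS4class{LabelVolume}.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of physical coordinates (um) of the voxel centres.
#' @export
voxelToPhysical <- function(v, idx) {
  idx <- rbind(idx)
  sweep((idx - 1) * spacingUm(v), 2, originUm(v), "+")
}

#' @rdname voxelToPhysical
#' @param xyz n x 3 matrix of physical coordinates (um).
#' @return for \code{physicalToVoxel}, n x 3 matrix of fractional 1-based
#'   voxel indices.
#' @export
physicalToVoxel <- function(v, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz, 2, originUm(v), "-") / spacingUm(v) + 1
}

#' Read / write volumes and labels
#'
#' Volumes are stored either as NIfTI (.nii / .nii.gz, via RNifti) or as
#' multipage TIFF stacks (one page per z slice, via the tiff package).
#' Spacing is taken from the NIfTI header when reading NIfTI; for TIFF it
#' must be supplied.
#'
#' @param path file path (.nii, .nii.gz, .tif or .tiff).
#' @param spacingUm voxel spacing for TIFF input/output.
#' @param bitDepth bit depth of the stored data.
#' @return \code{readVolume} returns a \linkS4class{Volume3D}.
#' @export
readVolume <- function(path, spacingUm = NULL, bitDepth = 16L) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1] * 1000  # NIfTI mm -> um
    if (!is.null(spacingUm)) sp <- spacingUm
    volume3d(array(as.numeric(img), dim(img)), spacingUm = sp,
             bitDepth = as.integer(bitDepth))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(pages)
    if (is.null(spacingUm))
      stop("spacingUm must be given for TIFF volumes")
    volume3d(array(as.numeric(arr), dim(arr)), spacingUm = spacingUm,
             bitDepth = as.integer(bitDepth))
  }
}

#' @rdname readVolume
#' @param v the \linkS4class{Volume3D} or \linkS4class{LabelVolume} to write.
#' @export
writeVolume <- function(v, path) {
  arr <- if (is(v, "LabelVolume")) labelArray(v) else voxels(v)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(spacingUm(v) / 1000, 3)
    RNifti::writeNifti(img, path)
  } else {
    depth <- if (is(v, "LabelVolume")) 16L else max(8L, bitDepth(v))
    scale <- 2^depth - 1
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) arr[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = depth)
  }
  invisible(path)
}
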