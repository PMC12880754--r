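#' @name accessors
#' @title Accessors for glomscale data classes
#' @description Slot accessors used throughout the package instead of direct
#'   slot access.
#' @param object an object of the relevant class.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object, ...) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacingUm", function(object, ...) standardGeneric("spacingUm"))

#' @rdname accessors
#' @export
setGeneric("originUm", function(object, ...) standardGeneric("originUm"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(object, ...) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(object, ...) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("labelKind", function(object, ...) standardGeneric("labelKind"))

#' @rdname accessors
#' @export
setGeneric("catalogue", function(object, ...) standardGeneric("catalogue"))

#' @rdname accessors
#' @export
setGeneric("distractors", function(object, ...) standardGeneric("distractors"))

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(object, ...) standardGeneric("truthLabels"))

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(object, ...) standardGeneric("sceneImage"))

#' @rdname accessors
#' @param which region name ("cortex", "medulla", "capsule").
#' @export
setGeneric("regionMask", function(object, which, ...) standardGeneric("regionMask"))

#' @rdname accessors
#' @export
setGeneric("transformToParent",
           function(object, ...) standardGeneric("transformToParent"))

#' @rdname accessors
#' @export
setGeneric("emaValue", function(object, ...) standardGeneric("emaValue"))

#' Apply a rigid+scale transform to points
#'
#' Maps moving-frame physical points (um) into the fixed frame.
#'
#' @param transform a \linkS4class{RigidScaleTransform}.
#' @param points numeric 3-vector or n x 3 matrix of moving-frame points (um).
#' @return points in the fixed frame, same shape as the input.
#' @export
setGeneric("applyTransform",
           function(transform, points) standardGeneric("applyTransform"))

#' Invert a rigid+scale transform
#'
#' @param transform a \linkS4class{RigidScaleTransform}.
#' @return the inverse \linkS4class{RigidScaleTransform}; composing the two
#'   is the identity to within 1e-6 um on test points.
#' @export
setGeneric("invertTransform",
           function(transform) standardGeneric("invertTransform"))
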