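#' Construct a rigid + isotropic-scale transform
#'
#' The transform maps moving-frame physical coordinates to fixed-frame ones
#' about a pair of manually selected common points (the fixed centres):
#' \code{x_f = c_f + Rz(thetaZ + thetaXY) * scale * (x_m - c_m) + t}.
#'
#' @param centreFixedUm,centreMovingUm common point (um) in each frame.
#' @param thetaZDeg primary rotation about z (degrees).
#' @param thetaXYDeg secondary in-plane rotation (degrees).
#' @param scale isotropic scale factor.
#' @param translationUm residual translation (um).
#' @return a \linkS4class{RigidScaleTransform}.
#' @examples
#' t <- rigidScaleTransform(thetaZDeg = 37.4)
#' applyTransform(t, c(10, 0, 0))
#' @export
rigidScaleTransform <- function(centreFixedUm = c(0, 0, 0),
                                centreMovingUm = c(0, 0, 0),
                                thetaZDeg = 0, thetaXYDeg = 0, scale = 1,
                                translationUm = c(0, 0, 0)) {
  new("RigidScaleTransform", centreFixedUm = as.numeric(centreFixedUm),
      centreMovingUm = as.numeric(centreMovingUm),
      thetaZDeg = as.numeric(thetaZDeg), thetaXYDeg = as.numeric(thetaXYDeg),
      scale = as.numeric(scale), translationUm = as.numeric(translationUm))
}

#' Identity transform
#' @return the identity \linkS4class{RigidScaleTransform}.
#' @export
identityTransform <- function() rigidScaleTransform()

totalThetaDeg <- function(t) t@thetaZDeg + t@thetaXYDeg

rotZ <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "RigidScaleTransform", function(transform, points) {
  p <- rbind(points)
  centred <- sweep(p, 2, transform@centreMovingUm, "-") * transform@scale
  rotated <- centred %*% t(rotZ(totalThetaDeg(transform)))
  out <- sweep(rotated, 2,
               transform@centreFixedUm + transform@translationUm, "+")
  if (is.null(dim(points))) out[1, ] else out
})

#' @rdname invertTransform
#' @export
setMethod("invertTransform", "RigidScaleTransform", function(transform) {
  # inverse maps fixed -> moving; express it in the same parameterisation
  # with the roles of the centres swapped and the translation folded in.
  tr <- -rotZ(-totalThetaDeg(transform)) %*%
    transform@translationUm / transform@scale
  rigidScaleTransform(centreFixedUm = transform@centreMovingUm,
                      centreMovingUm = transform@centreFixedUm,
                      thetaZDeg = -transform@thetaZDeg,
                      thetaXYDeg = -transform@thetaXYDeg,
                      scale = 1 / transform@scale,
                      translationUm = as.numeric(tr))
})

setMethod("show", "RigidScaleTransform", function(object) {
  cat(sprintf(
    "RigidScaleTransform: thetaZ %.3f deg, thetaXY %.3f deg, scale %.4f\n",
    object@thetaZDeg, object@thetaXYDeg, object@scale))
  cat(sprintf("  centre fixed  (um): %s\n",
              paste(signif(object@centreFixedUm, 6), collapse = ", ")))
  cat(sprintf("  centre moving (um): %s\n",
              paste(signif(object@centreMovingUm, 6), collapse = ", ")))
  cat(sprintf("  translation   (um): %s\n",
              paste(signif(object@translationUm, 6), collapse = ", ")))
})

#' Serialise / deserialise transforms as JSON
#'
#' All fields are written in physical micrometres and degrees under the
#' fixed-centre convention documented in \linkS4class{RigidScaleTransform}.
#'
#' @param transform a \linkS4class{RigidScaleTransform}.
#' @param path JSON file path.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(list(
    centre_fixed_um = transform@centreFixedUm,
    centre_moving_um = transform@centreMovingUm,
    theta_z_deg = transform@thetaZDeg,
    theta_xy_deg = transform@thetaXYDeg,
    scale = transform@scale,
    translation_um = transform@translationUm), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @return \code{readTransform} returns the \linkS4class{RigidScaleTransform}.
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidScaleTransform(centreFixedUm = x$centre_fixed_um,
                      centreMovingUm = x$centre_moving_um,
                      thetaZDeg = x$theta_z_deg, thetaXYDeg = x$theta_xy_deg,
                      scale = x$scale, translationUm = x$translation_um)
}
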