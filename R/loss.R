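#' Loss configuration for segmentation training
#'
#' The training objective is an ensemble of mean voxel-wise binary
#' cross-entropy and a weighted soft-Dice loss,
#' \deqn{L = CE + \beta \left(1 - \frac{2\sum p q + \varepsilon_1}
#'       {\sum p + \sum q + \varepsilon_2}\right),}
#' with the Dice weight \eqn{\beta = 1} by default so regional-overlap and
#' voxel-level terms contribute comparably, and smoothing constants
#' \eqn{\varepsilon_1 = \varepsilon_2 = 10^{-5}} guarding the empty-target
#' case.
#'
#' @param beta weight of the Dice term (default 1).
#' @param eps1 numerator smoothing constant (default 1e-5).
#' @param eps2 denominator smoothing constant (default 1e-5).
#' @return a LossConfig object.
#' @export
lossConfig <- function(beta = 1, eps1 = 1e-5, eps2 = 1e-5) {
  stopifnot(beta >= 0, eps1 > 0, eps2 > 0)
  structure(list(beta = beta, eps1 = eps1, eps2 = eps2),
            class = "LossConfig")
}

#' Combined cross-entropy + soft-Dice loss
#'
#' @param predProbs per-voxel foreground probabilities in (0, 1), array or
#'   vector.
#' @param target binary labels of the same shape.
#' @param cfg a \code{\link{lossConfig}}.
#' @return the scalar loss (non-negative up to epsilon effects).
#' @examples
#' p <- rep(1 - 1e-7, 8); q <- rep(1, 8)
#' combinedLoss(p, q, lossConfig())  # near 0 for a perfect prediction
#' @export
combinedLoss <- function(predProbs, target, cfg = lossConfig()) {
  if (length(predProbs) != length(target))
    stop("prediction and target shapes differ")
  if (!is.null(dim(predProbs)) && !is.null(dim(target)) &&
      !identical(dim(predProbs), dim(target)))
    stop("prediction and target shapes differ")
  p <- as.numeric(predProbs)
  q <- as.numeric(target)
  if (any(p <= 0 | p >= 1)) stop("predicted probabilities must lie in (0, 1)")
  ce <- -mean(q * log(p) + (1 - q) * log1p(-p))
  diceLoss <- 1 - (2 * sum(p * q) + cfg$eps1) / (sum(p) + sum(q) + cfg$eps2)
  ce + cfg$beta * diceLoss
}

#' Construct an EMA tracker for validation Dice
#'
#' @param alpha smoothing factor (default 0.9).
#' @return an \linkS4class{EmaTracker} with no value yet.
#' @export
emaTracker <- function(alpha = 0.9) new("EmaTracker", alpha = alpha)

#' Update an EMA tracker
#'
#' The first update sets the tracked value to the raw value; afterwards
#' \code{current <- alpha * current + (1 - alpha) * new}. A constant input
#' sequence is a fixed point.
#'
#' @param tracker an \linkS4class{EmaTracker}.
#' @param newValue new raw validation Dice in [0, 1].
#' @return the updated \linkS4class{EmaTracker}.
#' @examples
#' t <- emaUpdate(emaTracker(), 0.7)   # first update: current = 0.7
#' emaValue(emaUpdate(t, 0.9))         # 0.9*0.7 + 0.1*0.9 = 0.72
#' @export
emaUpdate <- function(tracker, newValue) {
  stopifnot(newValue >= 0, newValue <= 1)
  if (length(tracker@current) == 0) {
    tracker@current <- newValue
  } else {
    tracker@current <- tracker@alpha * tracker@current +
      (1 - tracker@alpha) * newValue
  }
  tracker
}

#' @rdname accessors
#' @export
setMethod("emaValue", "EmaTracker", function(object, ...) {
  if (length(object@current) == 0) NA_real_ else object@current
})

setMethod("show", "EmaTracker", function(object) {
  cat(sprintf("EmaTracker alpha=%.2f, current=%s\n", object@alpha,
              if (length(object@current)) format(object@current) else "unset"))
})
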