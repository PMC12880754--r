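#' Pluggable segmentation backbone
#'
#' Any backbone usable by the training and inference machinery implements
#' two operations: fit on a set of 3D patches with binary labels
#' (\code{\link{trainBackbone}}) and predict per-voxel foreground
#' probabilities on one patch (\code{\link{predictPatch}}). The pipeline
#' never assumes anything else about the model, so heavier architectures
#' can be dropped in behind the same contract.
#'
#' The reference backbone shipped here is deliberately lightweight so that
#' the full multiscale pipeline runs on a single CPU: a logistic voxel
#' classifier over fixed multiscale convolutional features (intensity,
#' Gaussian smoothings at two scales, a difference-of-Gaussians band-pass
#' and a local standard deviation), trained by momentum gradient descent on
#' the combined cross-entropy + soft-Dice objective with a polynomial
#' learning-rate decay.
#'
#' @name backbone
NULL

#' @describeIn backbone construct the reference backbone. \code{sigmasUm}
#'   are the two Gaussian feature scales in micrometres: physical rather
#'   than voxel units, so a model warm-started at a lower resolution sees
#'   the same physical features its weights were trained on.
#' @param sigmasUm Gaussian feature scales (um).
#' @return a GlomBackbone object.
#' @export
referenceBackbone <- function(sigmasUm = c(20, 40)) {
  structure(list(weights = rep(0, 6), sigmasUm = sigmasUm,
                 trained = FALSE),
            class = "GlomBackbone")
}

#' @export
print.GlomBackbone <- function(x, ...) {
  cat(sprintf("GlomBackbone (logistic multiscale-feature classifier), %s\n",
              if (x$trained) "trained" else "untrained"))
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

# normalise a patch image to [0,1] by its bit depth
normalisePatch <- function(image) {
  arr <- voxels(image)
  depth <- bitDepth(image)
  if (depth > 0) arr / (2^depth - 1) else arr
}

# feature matrix (nVoxel x 6) for one normalised intensity array; feature
# scales are fixed in physical units and converted by the voxel spacing
backboneFeatures <- function(backbone, arr, spacingUm) {
  dims <- dim(arr)
  s <- backbone$sigmasUm / spacingUm
  g1 <- cpp_gaussian_blur(arr, dims, s[1])
  g2 <- cpp_gaussian_blur(arr, dims, s[2])
  m2 <- cpp_gaussian_blur(arr^2, dims, s[1])
  localSd <- sqrt(pmax(m2 - g1^2, 0))
  cbind(1, as.numeric(arr), as.numeric(g1), as.numeric(g2),
        as.numeric(arr - g2), as.numeric(localSd))
}

#' @describeIn backbone per-voxel foreground probabilities for one patch.
#' @param backbone a backbone object.
#' @param image a \linkS4class{Volume3D} patch.
#' @return array of probabilities in [0, 1] with the patch dimensions.
#' @export
predictPatch <- function(backbone, image) {
  arr <- normalisePatch(image)
  f <- backboneFeatures(backbone, arr, spacingUm(image))
  array(stats::plogis(as.numeric(f %*% backbone$weights)), dim(arr))
}

# clamp probabilities away from {0,1} for the loss
clampProbs <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# analytic gradient of the combined loss w.r.t. the logits z (vectorised):
# dCE/dz = (p - q)/n through the sigmoid; the Dice term goes through
# dD/dp = -(2 q den - num)/den^2 and dp/dz = p (1 - p).
combinedLossGrad <- function(p, q, cfg) {
  n <- length(p)
  num <- 2 * sum(p * q) + cfg$eps1
  den <- sum(p) + sum(q) + cfg$eps2
  dDice <- -(2 * q * den - num) / den^2
  (p - q) / n + cfg$beta * dDice * p * (1 - p)
}

#' Hard Dice of thresholded predictions against binary labels
#'
#' Thresholds probabilities at 0.5 and computes the overlap Dice. Used for
#' validation tracking during training.
#' @param probs probability array/vector.
#' @param target binary labels.
#' @return Dice in [0, 1]; 1 when both sides are empty.
#' @export
hardDice <- function(probs, target) {
  p <- as.numeric(probs) >= 0.5
  q <- as.numeric(target) > 0
  s <- sum(p) + sum(q)
  if (s == 0) return(1)
  2 * sum(p & q) / s
}

#' @describeIn backbone fit the backbone on labelled patches by momentum
#'   gradient descent on the combined loss. Optionally tracks hard Dice on
#'   validation patches with an exponential moving average and retains the
#'   best-EMA-epoch weights.
#' @param patches list of \linkS4class{Patch} (training set).
#' @param valPatches optional list of \linkS4class{Patch} for validation.
#' @param epochs training epochs; 0 returns the model unchanged.
#' @param lr initial learning rate (polynomial decay, power 0.9).
#' @param momentum momentum coefficient.
#' @param lossCfg a \code{\link{lossConfig}}.
#' @param seed integer seed controlling patch order.
#' @param keepBest retain the weights from the best EMA-validation epoch
#'   (requires \code{valPatches}).
#' @return list with elements \code{model} (the fitted backbone),
#'   \code{history} (per-epoch data.frame: epoch, trainLoss, valDice,
#'   valDiceEma) and \code{bestEpoch}.
#' @export
trainBackbone <- function(backbone, patches, valPatches = NULL,
                          epochs = 20L, lr = 20, momentum = 0.9,
                          lossCfg = lossConfig(), seed = 1L,
                          keepBest = TRUE) {
  epochs <- as.integer(epochs)
  if (epochs == 0L)
    return(list(model = backbone,
                history = data.frame(epoch = integer(0),
                                     trainLoss = numeric(0),
                                     valDice = numeric(0),
                                     valDiceEma = numeric(0)),
                bestEpoch = NA_integer_))
  set.seed(seed)
  feats <- lapply(patches, function(p)
    backboneFeatures(backbone, normalisePatch(p@image),
                     spacingUm(p@image)))
  targs <- lapply(patches, function(p) as.numeric(labelArray(p@labels) > 0))
  valFeats <- lapply(valPatches, function(p)
    backboneFeatures(backbone, normalisePatch(p@image),
                     spacingUm(p@image)))
  valTargs <- lapply(valPatches, function(p)
    as.numeric(labelArray(p@labels) > 0))

  w <- backbone$weights
  vel <- rep(0, length(w))
  tracker <- emaTracker()
  hist <- data.frame(epoch = seq_len(epochs), trainLoss = NA_real_,
                     valDice = NA_real_, valDiceEma = NA_real_)
  bestW <- w
  bestEma <- -Inf
  bestEpoch <- NA_integer_
  for (e in seq_len(epochs)) {
    lrE <- lr * (1 - (e - 1) / epochs)^0.9
    ord <- sample.int(length(patches))
    losses <- numeric(length(ord))
    for (m in seq_along(ord)) {
      i <- ord[m]
      p <- clampProbs(stats::plogis(as.numeric(feats[[i]] %*% w)))
      q <- targs[[i]]
      losses[m] <- combinedLoss(p, q, lossCfg)
      g <- as.numeric(crossprod(feats[[i]], combinedLossGrad(p, q, lossCfg)))
      vel <- momentum * vel - lrE * g
      w <- w + vel
    }
    hist$trainLoss[e] <- mean(losses)
    if (length(valFeats)) {
      vp <- unlist(lapply(valFeats, function(f)
        stats::plogis(as.numeric(f %*% w))))
      vq <- unlist(valTargs)
      vd <- hardDice(vp, vq)
      tracker <- emaUpdate(tracker, vd)
      hist$valDice[e] <- vd
      hist$valDiceEma[e] <- emaValue(tracker)
      if (emaValue(tracker) > bestEma) {
        bestEma <- emaValue(tracker)
        bestW <- w
        bestEpoch <- e
      }
    }
  }
  out <- backbone
  out$weights <- if (keepBest && length(valFeats)) bestW else w
  out$trained <- TRUE
  list(model = out, history = hist, bestEpoch = bestEpoch)
}
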