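#' Training configuration
#'
#' @param nFolds cross-validation folds (default 5).
#' @param epochs training epochs per fold.
#' @param lr initial learning rate.
#' @param patchEdge training patch edge in voxels (default 128).
#' @param seed root seed for fold assignment and patch order.
#' @param mode "scratch" or "finetune".
#' @return a TrainConfig object.
#' @export
trainConfig <- function(nFolds = 5L, epochs = 20L, lr = 20, patchEdge = 128L,
                        seed = 1L, mode = c("scratch", "finetune")) {
  mode <- match.arg(mode)
  stopifnot(nFolds >= 2, epochs >= 0)
  structure(list(nFolds = as.integer(nFolds), epochs = as.integer(epochs),
                 lr = lr, patchEdge = as.integer(patchEdge),
                 seed = as.integer(seed), mode = mode),
            class = "TrainConfig")
}

#' Cross-validated backbone training
#'
#' Folds partition the parent cubes (never individual patches, so no patch
#' of a validation cube leaks into training). Each fold trains the backbone
#' on the remaining cubes' patches, tracks EMA validation Dice per epoch and
#' keeps the best-EMA-epoch model.
#'
#' @param cubes list of \linkS4class{AnnotatedCube}.
#' @param backbone starting backbone (untrained for scratch mode, a trained
#'   model for fine-tuning).
#' @param cfg a \code{\link{trainConfig}}.
#' @param lossCfg a \code{\link{lossConfig}}.
#' @return a CVReport: list with \code{foldAssignment} (cube index ->
#'   fold), \code{history} (per fold/epoch losses and EMA val Dice),
#'   \code{models} (best model per fold), \code{bestEpochs},
#'   \code{meanValDice}, \code{sdValDice}.
#' @export
runCV <- function(cubes, backbone = referenceBackbone(),
                  cfg = trainConfig(), lossCfg = lossConfig()) {
  if (length(cubes) < cfg$nFolds)
    stop("fewer cubes than folds")
  set.seed(cfg$seed)
  fold <- sample(rep_len(seq_len(cfg$nFolds), length(cubes)))
  models <- vector("list", cfg$nFolds)
  hist <- list()
  bestEpochs <- integer(cfg$nFolds)
  foldDice <- numeric(cfg$nFolds)
  for (f in seq_len(cfg$nFolds)) {
    trainPatches <- unlist(lapply(cubes[fold != f], extractPatches,
                                  patchEdge = cfg$patchEdge),
                           recursive = FALSE)
    valPatches <- unlist(lapply(cubes[fold == f], extractPatches,
                                patchEdge = cfg$patchEdge),
                         recursive = FALSE)
    fit <- trainBackbone(backbone, trainPatches, valPatches,
                         epochs = cfg$epochs, lr = cfg$lr,
                         lossCfg = lossCfg, seed = cfg$seed + f)
    models[[f]] <- fit$model
    bestEpochs[f] <- fit$bestEpoch
    h <- fit$history
    h$fold <- f
    hist[[f]] <- h
    foldDice[f] <- max(h$valDiceEma, na.rm = TRUE)
  }
  structure(list(foldAssignment = fold, history = do.call(rbind, hist),
                 models = models, bestEpochs = bestEpochs,
                 meanValDice = mean(foldDice), sdValDice = stats::sd(foldDice)),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport: %d folds, mean EMA val Dice %.3f (sd %.3f)\n",
              length(x$models), x$meanValDice, x$sdValDice))
  invisible(x)
}

#' Sliding-window inference over a full volume
#'
#' Overlapping windows are predicted independently and blended by uniform
#' averaging of the per-voxel accumulated probabilities; blend weights sum
#' to one everywhere. Volumes smaller than the window are reflected-padded
#' to the window size and the output cropped back.
#'
#' @param model a backbone (see \code{\link{predictPatch}}).
#' @param v a \linkS4class{Volume3D}.
#' @param window window edge (voxels).
#' @param overlapFraction fractional window overlap in each axis
#'   (default 0.5).
#' @return a probability \linkS4class{Volume3D} (bitDepth 0) in [0, 1].
#' @export
slidingWindowInfer <- function(model, v, window = 128L,
                               overlapFraction = 0.5) {
  window <- as.integer(window)
  arr <- voxels(v)
  d0 <- dim(arr)
  pad <- pmax(window - d0, 0L)
  if (any(pad > 0)) {
    # reflect-pad up to the window size
    padAxis <- function(a, axis, n) {
      if (n == 0) return(a)
      idx <- lapply(dim(a), seq_len)
      take <- idx
      take[[axis]] <- dim(a)[axis] - seq_len(n) + 1L
      abind0 <- do.call(`[`, c(list(a), take, list(drop = FALSE)))
      rev_idx <- lapply(dim(abind0), seq_len)
      rev_idx[[axis]] <- rev(seq_len(dim(abind0)[axis]))
      mirror <- do.call(`[`, c(list(abind0), rev_idx, list(drop = FALSE)))
      out <- array(0, dim(a) + c(axis == 1, axis == 2, axis == 3) * n)
      put <- lapply(dim(a), seq_len)
      out[put[[1]], put[[2]], put[[3]]] <- a
      tail_idx <- lapply(dim(out), seq_len)
      tail_idx[[axis]] <- dim(a)[axis] + seq_len(n)
      out[tail_idx[[1]], tail_idx[[2]], tail_idx[[3]]] <- mirror
      out
    }
    for (ax in 1:3) arr <- padAxis(arr, ax, pad[ax])
  }
  d <- dim(arr)
  stride <- max(1L, as.integer(round(window * (1 - overlapFraction))))
  starts <- function(n) {
    s <- seq(1L, max(n - window + 1L, 1L), by = stride)
    if (s[length(s)] != n - window + 1L) s <- c(s, n - window + 1L)
    unique(s)
  }
  sx <- starts(d[1]); sy <- starts(d[2]); sz <- starts(d[3])
  acc <- array(0, d)
  wt <- array(0, d)
  tpl <- volume3d(array(0, rep(window, 3)), spacingUm = spacingUm(v),
                  bitDepth = bitDepth(v))
  for (z in sz) for (y in sy) for (x in sx) {
    rx <- x:(x + window - 1L); ry <- y:(y + window - 1L)
    rz <- z:(z + window - 1L)
    tpl@voxels <- arr[rx, ry, rz, drop = FALSE]
    probs <- predictPatch(model, tpl)
    acc[rx, ry, rz] <- acc[rx, ry, rz] + probs
    wt[rx, ry, rz] <- wt[rx, ry, rz] + 1
  }
  out <- acc / wt
  out <- out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  volume3d(out, spacingUm = spacingUm(v), bitDepth = 0L,
           originUm = originUm(v))
}

# round-half-up (0.5 always rounds up, unlike R's banker rounding)
roundHalfUp <- function(x) floor(x + 0.5)

#' Filter pseudo-labelled training cubes by label content
#'
#' Glomeruli are sparse, so pseudo-labelled cube sets are dominated by empty
#' or near-empty cubes that bias training. At the intermediate resolution
#' all non-empty cubes are kept plus a uniform-random 1.05\% of the empty
#' ones; at the low resolution all cubes with label density >= 1\% are kept
#' plus a uniform-random 0.7\% of the sparser ones. Retained counts are
#' rounded half-up with a minimum of one when the pool is non-empty.
#'
#' @param cubes list of \linkS4class{AnnotatedCube} with labels.
#' @param level "intermediate" or "low".
#' @param seed integer seed for the uniform subsample.
#' @return the filtered list of cubes (original order preserved).
#' @export
filterTrainingCubes <- function(cubes, level = c("intermediate", "low"),
                                seed = 1L) {
  level <- match.arg(level)
  density <- vapply(cubes, function(cb) mean(labelArray(cb@labels) > 0),
                    numeric(1))
  if (level == "intermediate") {
    keepAll <- density > 0
    rate <- 0.0105
  } else {
    keepAll <- density >= 0.01
    rate <- 0.007
  }
  pool <- which(!keepAll)
  nKeep <- if (length(pool)) max(1L, roundHalfUp(rate * length(pool))) else 0L
  set.seed(seed)
  kept <- sort(c(which(keepAll),
                 if (nKeep > 0) sample(pool, min(nKeep, length(pool)))))
  cubes[kept]
}

#' Fine-tune a trained backbone on pseudo-labelled cubes
#'
#' Warm-starts from the previous level's weights and trains with the same
#' patching and loss as the scratch stage; an optional learning-rate restart
#' is supported through \code{cfg$lr}. Zero epochs return the model
#' unchanged.
#'
#' @param model a trained backbone.
#' @param cubes pseudo-labelled \linkS4class{AnnotatedCube} list.
#' @param cfg a \code{\link{trainConfig}} (mode "finetune").
#' @param lossCfg a \code{\link{lossConfig}}.
#' @param valCubes optional validation cubes.
#' @return list as from \code{\link{trainBackbone}}.
#' @export
fineTune <- function(model, cubes, cfg = trainConfig(mode = "finetune"),
                     lossCfg = lossConfig(), valCubes = NULL) {
  patches <- unlist(lapply(cubes, extractPatches, patchEdge = cfg$patchEdge),
                    recursive = FALSE)
  valPatches <- if (length(valCubes))
    unlist(lapply(valCubes, extractPatches, patchEdge = cfg$patchEdge),
           recursive = FALSE) else NULL
  trainBackbone(model, patches, valPatches, epochs = cfg$epochs,
                lr = cfg$lr, lossCfg = lossCfg, seed = cfg$seed)
}
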