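#' Dice overlap between two binary masks
#'
#' \code{2|P & T| / (|P| + |T|)}. Two empty masks score 1 (needed for
#' glomeruli-free evaluation cubes where an empty prediction is perfect).
#'
#' @param pred,truth binary arrays or \linkS4class{LabelVolume}s of the same
#'   shape (any non-zero voxel is foreground).
#' @return Dice score in [0, 1].
#' @examples
#' diceScore(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)))  # 1
#' @export
diceScore <- function(pred, truth) {
  p <- if (is(pred, "LabelVolume")) labelArray(pred) else pred
  q <- if (is(truth, "LabelVolume")) labelArray(truth) else truth
  if (!identical(dim(p), dim(q))) stop("shape mismatch")
  p <- p > 0
  q <- q > 0
  s <- sum(p) + sum(q)
  if (s == 0) return(1)
  2 * sum(p & q) / s
}

#' Label connected components of a binary prediction
#'
#' Components are found under 26-connectivity by default (appropriate for
#' isotropic data; 6-connectivity is available and splits corner-touching
#' structures). Instance IDs are assigned 1..K in order of decreasing voxel
#' count.
#'
#' @param binary a binary \linkS4class{LabelVolume} (or 0/1 array with
#'   spacing metadata lost).
#' @param connectivity 26 (default) or 6.
#' @return an instance \linkS4class{LabelVolume}.
#' @export
labelInstances <- function(binary, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  arr <- if (is(binary, "LabelVolume")) labelArray(binary) else binary
  sp <- if (is(binary, "LabelVolume")) spacingUm(binary) else 1
  org <- if (is(binary, "LabelVolume")) originUm(binary) else c(0, 0, 0)
  dims <- dim(arr)
  raw <- cpp_label_components(array(as.integer(arr > 0), dims), dims,
                              as.integer(connectivity))
  k <- max(raw)
  if (k > 0) {
    sizes <- tabulate(raw[raw > 0], nbins = k)
    remap <- integer(k)
    remap[order(sizes, decreasing = TRUE)] <- seq_len(k)
    raw[raw > 0] <- remap[raw[raw > 0]]
  }
  labelVolume(array(as.integer(raw), dims), spacingUm = sp, originUm = org,
              kind = "instance")
}

# surface area (um^2) of a binary instance mask by the coarea estimator:
# smooth the indicator and integrate the gradient magnitude. Accurate to a
# few percent on digital spheres at the default sigma.
surfaceAreaUm2 <- function(mask, spacingUm, sigma = 1.5) {
  d <- dim(mask)
  pad <- ceiling(3 * sigma) + 1
  padded <- array(0, d + 2 * pad)
  padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  sm <- cpp_gaussian_blur(padded, dim(padded), sigma)
  dp <- dim(padded)
  gx <- (sm[c(2:dp[1], dp[1]), , ] - sm[c(1, 1:(dp[1] - 1)), , ]) / 2
  gy <- (sm[, c(2:dp[2], dp[2]), ] - sm[, c(1, 1:(dp[2] - 1)), ]) / 2
  gz <- (sm[, , c(2:dp[3], dp[3])] - sm[, , c(1, 1:(dp[3] - 1))]) / 2
  sum(sqrt(gx^2 + gy^2 + gz^2)) * spacingUm^2
}

#' Split touching instances by distance-transform watershed
#'
#' Quasi-spherical units that lie closer than the grid resolution merge
#' into one connected component. This step re-separates them: within each
#' instance, the Euclidean distance transform to the background is
#' computed, core markers are the components where the distance reaches
#' \code{markerFraction} of the minimum credible glomerular radius, and
#' when an instance holds two or more cores its voxels are reassigned to
#' the nearest core by descending-distance region growing (a marker-based
#' watershed). Instances with fewer than two cores are left untouched, so
#' the operation never merges anything.
#'
#' @param instances an instance \linkS4class{LabelVolume}.
#' @param minRadiusUm minimum credible unit radius (um, default 62).
#' @param markerFraction fraction of \code{minRadiusUm} the core distance
#'   must reach (default 0.7).
#' @return the relabelled instance \linkS4class{LabelVolume} (IDs 1..K by
#'   decreasing size).
#' @export
splitTouchingInstances <- function(instances, minRadiusUm = 62,
                                   markerFraction = 0.7) {
  lab <- labelArray(instances)
  sp <- spacingUm(instances)
  dims <- dim(lab)
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, dims)
  nextId <- 0L
  coreVox <- markerFraction * minRadiusUm / sp
  for (id in ids) {
    idx <- which(lab == id)
    ijk <- arrayInd(idx, dims)
    lo <- pmax(apply(ijk, 2, min) - 1L, 1L)
    hi <- pmin(apply(ijk, 2, max) + 1L, dims)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == id
    sd3 <- dim(sub)
    edt <- cpp_edt(array(as.integer(!sub), sd3), sd3)
    markers <- cpp_label_components(array(as.integer(sub & edt >= coreVox),
                                          sd3), sd3, 26L)
    nCores <- max(markers)
    if (nCores < 2L) {
      assign <- array(0L, sd3)
      assign[sub] <- 1L
      nCores <- 1L
    } else {
      # grow the cores outward in order of decreasing distance so the
      # watershed line falls on the neck
      assign <- array(as.integer(markers), sd3)
      todo <- which(sub & assign == 0L)
      todo <- todo[order(edt[todo], decreasing = TRUE)]
      offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
      offs <- offs[rowSums(abs(offs)) > 0, ]
      pass <- 0L
      while (length(todo) && pass < 100L) {
        pass <- pass + 1L
        remaining <- integer(0)
        for (v in todo) {
          vi <- arrayInd(v, sd3)
          nb <- sweep(offs, 2, as.integer(vi), "+")
          ok <- nb[, 1] >= 1 & nb[, 1] <= sd3[1] & nb[, 2] >= 1 &
            nb[, 2] <= sd3[2] & nb[, 3] >= 1 & nb[, 3] <= sd3[3]
          nbi <- nb[ok, , drop = FALSE]
          labs <- assign[cbind(nbi[, 1], nbi[, 2], nbi[, 3])]
          labs <- labs[labs > 0]
          if (length(labs)) {
            assign[v] <- as.integer(names(sort(table(labs),
                                               decreasing = TRUE))[1])
          } else {
            remaining <- c(remaining, v)
          }
        }
        if (length(remaining) == length(todo)) break
        todo <- remaining
      }
      if (length(todo)) assign[todo] <- 1L  # isolated leftovers
    }
    for (core in seq_len(nCores)) {
      sel <- assign == core
      if (!any(sel)) next
      nextId <- nextId + 1L
      piece <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      piece[sel] <- nextId
      out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- piece
    }
  }
  # relabel by decreasing size for a stable ordering
  if (nextId > 0) {
    sizes <- tabulate(out[out > 0], nbins = nextId)
    remap <- integer(nextId)
    remap[order(sizes, decreasing = TRUE)] <- seq_len(nextId)
    out[out > 0] <- remap[out[out > 0]]
  }
  labelVolume(out, spacingUm = sp, originUm = originUm(instances),
              kind = "instance")
}

#' Per-instance intensity and morphological properties
#'
#' For each instance: voxel count, physical volume, equivalent spherical
#' radius \code{(3V/4pi)^(1/3)}, population variance of member intensities,
#' and roundness measured as 3D sphericity
#' \code{pi^(1/3) (6V)^(2/3) / A} with the surface area A from a smoothed
#' surface estimator (clamped to (0, 1]). Single-voxel instances get
#' variance 0 and roundness 1 by convention.
#'
#' @param instances an instance \linkS4class{LabelVolume}.
#' @param image the matching \linkS4class{Volume3D}.
#' @param cortexMask optional logical array; fills the \code{in_cortex}
#'   column from centroid membership.
#' @return an instance table: data.frame with columns instance_id,
#'   x_um, y_um, z_um, voxel_count, volume_um3, equivalent_radius_um,
#'   intensity_variance, roundness, neighbour_count (NA until
#'   \code{\link{neighbourhoodCount}}), in_cortex.
#' @export
computeProperties <- function(instances, image, cortexMask = NULL) {
  if (!identical(dim(labelArray(instances)), dim(voxels(image))))
    stop("instances and image grids differ")
  lab <- labelArray(instances)
  img <- voxels(image)
  sp <- spacingUm(instances)
  org <- originUm(instances)
  ids <- sort(unique(lab[lab > 0]))
  n <- length(ids)
  out <- data.frame(instance_id = ids, x_um = numeric(n), y_um = numeric(n),
                    z_um = numeric(n), voxel_count = integer(n),
                    volume_um3 = numeric(n),
                    equivalent_radius_um = numeric(n),
                    intensity_variance = numeric(n), roundness = numeric(n),
                    neighbour_count = rep(NA_integer_, n),
                    in_cortex = rep(NA, n))
  if (n == 0) return(out)
  idxAll <- which(lab > 0)
  byId <- split(idxAll, lab[idxAll])
  dims <- dim(lab)
  for (r in seq_len(n)) {
    idx <- byId[[as.character(ids[r])]]
    ijk <- arrayInd(idx, dims)
    ctr <- (colMeans(ijk) - 1) * sp + org
    out$x_um[r] <- ctr[1]; out$y_um[r] <- ctr[2]; out$z_um[r] <- ctr[3]
    cnt <- length(idx)
    out$voxel_count[r] <- cnt
    vol <- cnt * sp^3
    out$volume_um3[r] <- vol
    out$equivalent_radius_um[r] <- (3 * vol / (4 * pi))^(1 / 3)
    vals <- img[idx]
    out$intensity_variance[r] <- if (cnt > 1)
      sum((vals - mean(vals))^2) / cnt else 0
    if (cnt == 1) {
      out$roundness[r] <- 1
    } else {
      lo <- apply(ijk, 2, min); hi <- apply(ijk, 2, max)
      sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == ids[r]
      area <- surfaceAreaUm2(sub, sp)
      out$roundness[r] <- min(pi^(1 / 3) * (6 * vol)^(2 / 3) / area, 1)
    }
    if (!is.null(cortexMask)) {
      vi <- pmin(pmax(round((ctr - org) / sp) + 1, 1), dims)
      out$in_cortex[r] <- cortexMask[vi[1], vi[2], vi[3]]
    }
  }
  out
}

#' Neighbourhood density counts for an instance table
#'
#' For each instance, counts the instance centroids (itself included)
#' lying inside the axis-aligned cube of edge \code{W} voxels centred on
#' its centroid. True glomeruli cluster in the cortex while false positives
#' are sparse, so a minimum count D discriminates at low contrast.
#'
#' @param table an instance table from \code{\link{computeProperties}}.
#' @param W window edge in voxels (>= 1).
#' @param spacingUm voxel spacing of the grid the table came from.
#' @return the table with \code{neighbour_count} filled in.
#' @export
neighbourhoodCount <- function(table, W, spacingUm) {
  stopifnot(W >= 1)
  half <- W * spacingUm / 2
  xyz <- as.matrix(table[, c("x_um", "y_um", "z_um")])
  n <- nrow(xyz)
  cnt <- integer(n)
  for (r in seq_len(n)) {
    d <- abs(sweep(xyz, 2, xyz[r, ], "-"))
    cnt[r] <- sum(d[, 1] <= half & d[, 2] <= half & d[, 3] <= half)
  }
  table$neighbour_count <- cnt
  table
}

#' Construct a threshold set
#'
#' @param varianceLower,varianceUpper intensity-variance bounds
#'   (NA = inactive).
#' @param roundnessMin minimum sphericity (NA = inactive).
#' @param radiusMinUm minimum equivalent radius (um); fixed at 62 by
#'   default, the smallest credible glomerular radius after tissue
#'   shrinkage (volume 1e6 um^3).
#' @param densityWindowW neighbourhood window edge W in voxels
#'   (NA = inactive).
#' @param densityMinCount minimum neighbour count D, self included
#'   (NA = inactive).
#' @param useCortexMask require centroids inside the cortex mask.
#' @return a \linkS4class{ThresholdSet}.
#' @export
thresholdSet <- function(varianceLower = NA_real_, varianceUpper = NA_real_,
                         roundnessMin = NA_real_, radiusMinUm = 62,
                         densityWindowW = NA_real_,
                         densityMinCount = NA_real_,
                         useCortexMask = FALSE) {
  new("ThresholdSet", varianceLower = as.numeric(varianceLower),
      varianceUpper = as.numeric(varianceUpper),
      roundnessMin = as.numeric(roundnessMin),
      radiusMinUm = as.numeric(radiusMinUm),
      densityWindowW = as.numeric(densityWindowW),
      densityMinCount = as.numeric(densityMinCount),
      useCortexMask = useCortexMask)
}

setMethod("show", "ThresholdSet", function(object) {
  fmt <- function(x) if (is.na(x)) "inactive" else format(signif(x, 6))
  cat("ThresholdSet:\n")
  cat("  variance bounds:", fmt(object@varianceLower), "..",
      fmt(object@varianceUpper), "\n")
  cat("  roundness min:  ", fmt(object@roundnessMin), "\n")
  cat("  radius min (um):", fmt(object@radiusMinUm), "\n")
  cat("  density W/D:    ", fmt(object@densityWindowW), "/",
      fmt(object@densityMinCount), "\n")
  cat("  cortex mask:    ", object@useCortexMask, "\n")
})

activeCriteria <- function(th) {
  sum(!is.na(th@varianceLower), !is.na(th@varianceUpper),
      !is.na(th@roundnessMin), !is.na(th@radiusMinUm),
      !is.na(th@densityWindowW) && !is.na(th@densityMinCount),
      th@useCortexMask)
}

# which rows of an instance table survive a threshold set
keptInstanceIds <- function(table, th, spacingUm) {
  keep <- rep(TRUE, nrow(table))
  if (!is.na(th@varianceLower))
    keep <- keep & table$intensity_variance >= th@varianceLower
  if (!is.na(th@varianceUpper))
    keep <- keep & table$intensity_variance <= th@varianceUpper
  if (!is.na(th@roundnessMin))
    keep <- keep & table$roundness >= th@roundnessMin
  if (!is.na(th@radiusMinUm))
    keep <- keep & table$equivalent_radius_um >= th@radiusMinUm
  if (!is.na(th@densityWindowW) && !is.na(th@densityMinCount)) {
    tab <- neighbourhoodCount(table, th@densityWindowW, spacingUm)
    keep <- keep & tab$neighbour_count >= th@densityMinCount
  }
  if (th@useCortexMask) {
    if (all(is.na(table$in_cortex)))
      stop("cortex mask requested but in_cortex is not filled ",
           "(pass cortexMask to computeProperties)")
    keep <- keep & table$in_cortex %in% TRUE
  }
  table$instance_id[keep]
}

#' Apply a threshold set to an instance segmentation
#'
#' Keeps an instance iff all active criteria hold: intensity variance
#' within bounds, roundness at least the minimum, equivalent radius at
#' least the floor, neighbour count at least D within the window W, and
#' centroid inside the cortex mask. With no active criteria this is the
#' identity on instances; tightening any single threshold never increases
#' the kept count.
#'
#' @param instances an instance \linkS4class{LabelVolume}.
#' @param table its instance table (from \code{\link{computeProperties}}).
#' @param th a \linkS4class{ThresholdSet}.
#' @param cortexMask logical array, required when \code{th@useCortexMask}
#'   and the table lacks \code{in_cortex}.
#' @return the filtered instance \linkS4class{LabelVolume}.
#' @export
applyThresholdSet <- function(instances, table, th, cortexMask = NULL) {
  if (th@useCortexMask && all(is.na(table$in_cortex))) {
    if (is.null(cortexMask))
      stop("cortex mask requested but absent")
    dims <- dim(labelArray(instances))
    sp <- spacingUm(instances); org <- originUm(instances)
    vi <- pmin(pmax(round(sweep(as.matrix(table[, c("x_um", "y_um", "z_um")]),
                                2, org, "-") / sp) + 1, 1),
               matrix(dims, nrow(table), 3, byrow = TRUE))
    table$in_cortex <- cortexMask[vi]
  }
  ids <- keptInstanceIds(table, th, spacingUm(instances))
  lab <- labelArray(instances)
  lab[!(lab %in% ids)] <- 0L
  labelVolume(lab, spacingUm = spacingUm(instances),
              originUm = originUm(instances), kind = "instance")
}

#' Latin-hypercube search over false-positive filter thresholds
#'
#' Sampling intervals for each tunable threshold are derived from
#' percentiles of the aggregate property distribution over all evaluation
#' predictions (lower bounds span P1-P30, upper bounds P70-P99 by
#' default). \code{nSets} stratified candidates are drawn (one sample per
#' equal-width stratum per dimension). Within each dimension the lowest
#' quarter of the unit interval deactivates the criterion and the rest
#' maps linearly onto the percentile interval, so the search explores
#' which criteria to apply as well as where to place them (the selected
#' operating points on real data likewise leave some criteria out at some
#' resolutions). Each candidate is scored by its mean Dice over the
#' evaluation cubes after filtering, and the best is returned; ties break
#' to fewer active criteria, then lower candidate index. A degenerate
#' (single-valued) property distribution collapses its interval and
#' deactivates that parameter everywhere.
#'
#' @param evalCubes list of evaluation cubes, each a list with elements
#'   \code{prediction} (binary \linkS4class{LabelVolume}), \code{truth}
#'   (binary \linkS4class{LabelVolume}), \code{image}
#'   (\linkS4class{Volume3D}) and optionally \code{cortexMask}. Glomeruli-
#'   free cubes (for example a fat-only cube) enter with an empty truth.
#' @param base a \linkS4class{ThresholdSet} holding the non-tunable
#'   criteria (radius floor, density window, cortex flag).
#' @param tunable character subset of c("varianceLower", "varianceUpper",
#'   "roundnessMin").
#' @param nSets number of LHS candidates (default 20).
#' @param percentileBounds list with \code{lower} and \code{upper}
#'   percentile spans.
#' @param seed integer seed for the LHS draw.
#' @return an LhsSearchResult: list with \code{candidates} (ThresholdSets),
#'   \code{scores} (mean Dice per candidate), \code{perCube} (matrix of
#'   Dice per candidate x cube), \code{best} (index),
#'   \code{bestThresholds}, \code{unfilteredDice} (per cube, before any
#'   filtering), and \code{samples} (the LHS design).
#' @export
lhsSearch <- function(evalCubes, base = thresholdSet(),
                      tunable = c("varianceLower", "varianceUpper",
                                  "roundnessMin"),
                      nSets = 20L,
                      percentileBounds = list(lower = c(1, 30),
                                              upper = c(70, 99)),
                      seed = 1L) {
  if (length(evalCubes) < 1) stop("need at least one evaluation cube")
  tunable <- match.arg(tunable, several.ok = TRUE)
  prep <- lapply(evalCubes, function(cb) {
    inst <- labelInstances(cb$prediction)
    tab <- computeProperties(inst, cb$image,
                             cortexMask = cb$cortexMask)
    list(instances = inst, table = tab, truth = cb$truth)
  })
  agg <- do.call(rbind, lapply(prep, `[[`, "table"))

  interval <- function(values, span) {
    values <- values[is.finite(values)]
    if (length(values) < 2) return(NULL)  # empty/degenerate: inactive
    qs <- stats::quantile(values, span / 100, names = FALSE, type = 7)
    if (!all(is.finite(qs)) || diff(qs) <= 0) NULL else qs
  }
  ivals <- list()
  for (dimName in tunable) {
    v <- switch(dimName,
                varianceLower = agg$intensity_variance,
                varianceUpper = agg$intensity_variance,
                roundnessMin = agg$roundness)
    span <- if (dimName == "varianceUpper") percentileBounds$upper
            else percentileBounds$lower
    ivals[[dimName]] <- interval(v, span)
  }
  activeDims <- names(Filter(Negate(is.null), ivals))
  k <- length(activeDims)
  set.seed(seed)
  u <- if (k > 0) lhs::randomLHS(nSets, k) else
    matrix(numeric(0), nSets, 0)
  colnames(u) <- activeDims

  inactiveFraction <- 0.25
  candidates <- vector("list", nSets)
  for (i in seq_len(nSets)) {
    th <- base
    for (dimName in activeDims) {
      ui <- u[i, dimName]
      if (ui < inactiveFraction) next  # criterion left out of this set
      iv <- ivals[[dimName]]
      val <- iv[1] + (ui - inactiveFraction) / (1 - inactiveFraction) *
        (iv[2] - iv[1])
      slot(th, dimName) <- val
    }
    candidates[[i]] <- th
  }

  scoreCube <- function(p, th) {
    filtered <- applyThresholdSet(p$instances, p$table, th)
    diceScore(filtered, p$truth)
  }
  perCube <- t(vapply(candidates, function(th)
    vapply(prep, scoreCube, numeric(1), th = th), numeric(length(prep))))
  perCube <- matrix(perCube, nrow = nSets)
  scores <- rowMeans(perCube)
  bestScore <- max(scores)
  tiedIdx <- which(scores >= bestScore - 1e-12)
  nActive <- vapply(candidates[tiedIdx], activeCriteria, numeric(1))
  best <- tiedIdx[order(nActive, tiedIdx)][1]

  unfiltered <- vapply(prep, function(p)
    diceScore(p$instances, p$truth), numeric(1))

  structure(list(candidates = candidates, scores = scores,
                 perCube = perCube, best = best,
                 bestThresholds = candidates[[best]],
                 unfilteredDice = unfiltered, samples = u),
            class = "LhsSearchResult")
}

#' @export
print.LhsSearchResult <- function(x, ...) {
  cat(sprintf(
    "LhsSearchResult: %d candidates, best mean Dice %.3f (unfiltered %.3f)\n",
    length(x$candidates), x$scores[x$best], mean(x$unfilteredDice)))
  invisible(x)
}

#' Published reference thresholds
#'
#' Loads the reference false-positive filter configurations reported for
#' real kidney predictions at the three resolution levels (shipped as
#' \code{reference_thresholds.json}). These document the operating point on
#' real data; they are not reproduced by the phantom.
#'
#' @return named list of \linkS4class{ThresholdSet} objects
#'   ("high", "intermediate", "low") plus the reported before/after Dice.
#' @export
referenceThresholds <- function() {
  path <- system.file("extdata", "reference_thresholds.json",
                      package = "glomscale")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(x$levels, function(lv) {
    thresholdSet(
      varianceLower = if (is.null(lv$variance_lower)) NA else lv$variance_lower,
      varianceUpper = if (is.null(lv$variance_upper)) NA else lv$variance_upper,
      roundnessMin = if (is.null(lv$roundness_min)) NA else lv$roundness_min,
      radiusMinUm = lv$radius_min_um,
      densityWindowW = if (is.null(lv$density_window_W)) NA else lv$density_window_W,
      densityMinCount = if (is.null(lv$density_min_count_D)) NA else lv$density_min_count_D,
      useCortexMask = isTRUE(lv$use_cortex_mask))
  })
  attr(out, "dice_before_after") <- x$dice_before_after
  out
}
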