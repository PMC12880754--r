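#' Glomerular centre density map by summation kernel
#'
#' Convolves a summation (box) kernel of edge \code{kernelEdge} voxels over
#' the glomerulus centre indicator: \code{counts[v]} is the number of
#' centres within the axis-aligned window centred at v. For fully interior
#' centres the counts sum to N x kernelEdge^3. The per-mm^3 field divides
#' by the physical window volume.
#'
#' @param centres n x 3 matrix of 1-based voxel coordinates of instance
#'   centres (fractional coordinates are assigned to their containing
#'   voxel).
#' @param gridShape 3-vector of grid dimensions.
#' @param kernelEdge odd window edge in voxels (default 31).
#' @param spacingUm voxel spacing (um).
#' @return a DensityMap: list with \code{counts} (3D array),
#'   \code{perMm3} (counts / window volume in mm^3), \code{kernelEdge},
#'   \code{spacingUm}.
#' @examples
#' dm <- densityMap(matrix(c(16, 16, 16), 1), c(31, 31, 31),
#'                  kernelEdge = 31, spacingUm = 25.08)
#' max(dm$perMm3)  # one centre in a (31 * 25.08 um)^3 window
#' @export
densityMap <- function(centres, gridShape, kernelEdge = 31L, spacingUm = 1) {
  kernelEdge <- as.integer(kernelEdge)
  stopifnot(kernelEdge %% 2L == 1L)
  gridShape <- as.integer(gridShape)
  ind <- array(0, gridShape)
  if (length(centres)) {
    centres <- rbind(centres)
    vi <- round(centres)
    if (any(vi < 1) || any(vi > matrix(gridShape, nrow(vi), 3, byrow = TRUE)))
      stop("centres must lie inside the grid")
    for (r in seq_len(nrow(vi)))
      ind[vi[r, 1], vi[r, 2], vi[r, 3]] <- ind[vi[r, 1], vi[r, 2], vi[r, 3]] + 1
  }
  counts <- cpp_box_sum(ind, gridShape, kernelEdge)
  windowMm3 <- (kernelEdge * spacingUm / 1000)^3
  structure(list(counts = counts, perMm3 = counts / windowMm3,
                 kernelEdge = kernelEdge, spacingUm = spacingUm),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf(
    "DensityMap %s, kernel %d^3, max %.3g centres/window (%.3g per mm^3)\n",
    paste(dim(x$counts), collapse = " x "), x$kernelEdge, max(x$counts),
    max(x$perMm3)))
  invisible(x)
}

#' Tripartite cortical zonation
#'
#' Splits the cortex into inner (juxtamedullary), middle (mid-cortical) and
#' outer (superficial) zones: the inner zone lies within three mean
#' glomerular diameters of the medulla, the outer zone within three
#' diameters of the capsule-side outer surface, the middle zone is the
#' remainder. Distances are Euclidean distance transforms from the medulla
#' mask and from the exterior (non-kidney) region. Where the cortex is
#' thinner than six diameters the bands overlap and the inner zone takes
#' precedence; a cortex with no middle zone anywhere triggers a warning.
#' The three masks are pairwise disjoint and their union is exactly the
#' cortex mask.
#'
#' @param cortexMask,medullaMask disjoint logical arrays on one grid.
#' @param meanDiameterUm mean glomerular diameter (um).
#' @param spacingUm voxel spacing (um).
#' @return a \linkS4class{ZonalPartition}.
#' @export
zonateCortex <- function(cortexMask, medullaMask, meanDiameterUm,
                         spacingUm = 1) {
  if (any(cortexMask & medullaMask))
    stop("cortex and medulla masks must be disjoint")
  dims <- dim(cortexMask)
  band <- 3 * meanDiameterUm
  dMed <- cpp_edt(array(as.integer(medullaMask), dims), dims) * spacingUm
  exterior <- !(cortexMask | medullaMask)
  dCap <- cpp_edt(array(as.integer(exterior), dims), dims) * spacingUm
  inner <- cortexMask & dMed <= band
  outer <- cortexMask & dCap <= band & !inner
  middle <- cortexMask & !inner & !outer
  if (!any(middle))
    warning("cortex thinner than six glomerular diameters everywhere: ",
            "middle zone is empty")
  new("ZonalPartition", inner = inner, middle = middle, outer = outer,
      bandWidthUm = band, spacingUm = spacingUm)
}

setMethod("show", "ZonalPartition", function(object) {
  v <- c(sum(object@inner), sum(object@middle), sum(object@outer))
  cat(sprintf(
    "ZonalPartition: band %.0f um; inner/middle/outer = %d/%d/%d voxels\n",
    object@bandWidthUm, v[1], v[2], v[3]))
})

#' Zonal glomerular statistics
#'
#' Assigns each instance to a cortical zone by centroid membership and
#' reports per-zone counts and volume statistics, the mean glomerular
#' diameter (twice the mean equivalent radius, the zonation input
#' upstream), and a Kruskal-Wallis test of volume across zones when all
#' three zones are populated. Empty zones report NA statistics rather than
#' zeros.
#'
#' @param table an instance table (see \code{\link{computeProperties}})
#'   with centroids on the partition grid.
#' @param partition a \linkS4class{ZonalPartition}.
#' @param originUm grid origin of the partition (um).
#' @return a ZonalStats: list with \code{zones} (per-zone data.frame:
#'   zone, count, median/mean/sd volume in um^3), \code{meanDiameterUm},
#'   \code{kruskal} (c(H, p) or NA), \code{cortexVolumeCm3}, and
#'   \code{assignment} (zone per instance).
#' @export
zonalStats <- function(table, partition, originUm = c(0, 0, 0)) {
  sp <- partition@spacingUm
  dims <- dim(partition@inner)
  n <- nrow(table)
  zone <- rep(NA_character_, n)
  if (n > 0) {
    vi <- round(sweep(as.matrix(table[, c("x_um", "y_um", "z_um")]), 2,
                      originUm, "-") / sp) + 1
    vi <- pmin(pmax(vi, 1), matrix(dims, n, 3, byrow = TRUE))
    for (r in seq_len(n)) {
      if (partition@inner[vi[r, 1], vi[r, 2], vi[r, 3]]) zone[r] <- "inner"
      else if (partition@middle[vi[r, 1], vi[r, 2], vi[r, 3]]) zone[r] <- "middle"
      else if (partition@outer[vi[r, 1], vi[r, 2], vi[r, 3]]) zone[r] <- "outer"
    }
  }
  zoneNames <- c("inner", "middle", "outer")
  zones <- do.call(rbind, lapply(zoneNames, function(z) {
    v <- table$volume_um3[zone %in% z]
    data.frame(zone = z, count = length(v),
               median_volume_um3 = if (length(v)) stats::median(v) else NA_real_,
               mean_volume_um3 = if (length(v)) mean(v) else NA_real_,
               sd_volume_um3 = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  groups <- lapply(zoneNames, function(z) table$volume_um3[zone %in% z])
  kw <- if (all(vapply(groups, length, integer(1)) > 0) && n >= 3)
    kruskalWallis(groups) else c(H = NA_real_, p = NA_real_)
  cortexVox <- sum(partition@inner) + sum(partition@middle) +
    sum(partition@outer)
  structure(list(zones = zones,
                 meanDiameterUm = 2 * mean(table$equivalent_radius_um),
                 kruskal = kw,
                 cortexVolumeCm3 = cortexVox * sp^3 / 1e12,
                 assignment = zone),
            class = "ZonalStats")
}

#' @export
print.ZonalStats <- function(x, ...) {
  cat("ZonalStats:\n")
  print(x$zones, row.names = FALSE)
  cat(sprintf("  mean diameter %.1f um; cortex %.3g cm^3\n",
              x$meanDiameterUm, x$cortexVolumeCm3))
  if (!is.na(x$kruskal["H"]))
    cat(sprintf("  Kruskal-Wallis H = %.3f, p = %.3g\n",
                x$kruskal["H"], x$kruskal["p"]))
  invisible(x)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction and a chi-squared reference
#' distribution with k-1 degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return named vector c(H, p).
#' @examples
#' kruskalWallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskalWallis <- function(groups) {
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("all groups must be non-empty")
  if (sum(lengths(groups)) < 3) stop("need at least 3 observations")
  values <- unlist(groups)
  if (length(unique(values)) == 1)  # all tied: H = 0 by convention
    return(c(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Sphere geometry: volume from radius and radius from volume
#'
#' \code{V = (4/3) pi r^3} and its inverse. Used for the 62 um minimum
#' glomerular radius (volume 1e6 um^3) and its MRI-based counterpart
#' (72 um, 1.6e6 um^3).
#'
#' @param volumeUm3,radiusUm positive scalars (um^3 / um).
#' @return the complementary quantity.
#' @examples
#' sphereRadiusFromVolume(1e6)   # ~62 um
#' sphereVolumeFromRadius(72)    # ~1.6e6 um^3
#' @export
sphereRadiusFromVolume <- function(volumeUm3) {
  if (any(volumeUm3 <= 0)) stop("volume must be positive")
  (3 * volumeUm3 / (4 * pi))^(1 / 3)
}

#' @rdname sphereRadiusFromVolume
#' @export
sphereVolumeFromRadius <- function(radiusUm) {
  if (any(radiusUm <= 0)) stop("radius must be positive")
  4 / 3 * pi * radiusUm^3
}
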