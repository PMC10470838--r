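#' Point-cloud filter chain configuration
#'
#' Parameters of the preprocessing chain applied before structural trait
#' extraction: statistical outlier removal, voxel downsampling of the
#' sub-canopy layer, and moving-least-squares smoothing.
#'
#' @param knn neighbour count for the outlier statistic (default 16).
#' @param std_multiplier standard-deviation multiple above the mean
#'   neighbour-distance statistic beyond which a point is an outlier
#'   (default 2).
#' @param voxel_size voxel edge, cm, for sub-canopy downsampling
#'   (default 0.25).
#' @param canopy_fraction fraction of the z range counted as "below the
#'   canopy" and voxel-filtered (default 0.5, in (0, 1)).
#' @param mls_radius neighbourhood radius, cm, for surface smoothing
#'   (default 1).
#' @return A `filter_config` list.
#' @export
filter_config <- function(knn = 16L, std_multiplier = 2, voxel_size = 0.25,
                          canopy_fraction = 0.5, mls_radius = 1) {
  stopifnot(knn >= 1, std_multiplier > 0, voxel_size > 0,
            canopy_fraction > 0, canopy_fraction < 1, mls_radius > 0)
  structure(list(knn = as.integer(knn), std_multiplier = std_multiplier,
                 voxel_size = voxel_size, canopy_fraction = canopy_fraction,
                 mls_radius = mls_radius),
            class = "filter_config")
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `knn` nearest neighbours and
#' drops points whose statistic exceeds mean + `std_multiplier` * sd of that
#' statistic over the cloud.
#'
#' @param cloud a [point_cloud] with more than `knn` points.
#' @param knn neighbour count.
#' @param std_multiplier standard-deviation multiple.
#' @return The filtered [point_cloud], with an attribute `removed` giving the
#'   indices of removed points.
#' @export
remove_outliers <- function(cloud, knn = 16L, std_multiplier = 2) {
  stopifnot(inherits(cloud, "point_cloud"), knn >= 1)
  n <- nrow(cloud$points)
  if (n <= knn)
    stop("cloud has ", n, " points; need more than knn = ", knn)
  stat <- .knn_mean_dist(cloud$points, as.integer(knn))
  cut <- mean(stat) + std_multiplier * stats::sd(stat)
  keep <- stat <= cut
  if (!any(keep)) stop("outlier filter would remove every point")
  out <- point_cloud(cloud$points[keep, , drop = FALSE], cloud$sample_id)
  attr(out, "removed") <- which(!keep)
  out
}

#' Voxel downsampling of the sub-canopy layer
#'
#' Points in the lower `canopy_fraction` of the cloud's z range are replaced
#' by one centroid per occupied voxel; points at or above the cut height pass
#' through unchanged.
#'
#' @param cloud a [point_cloud].
#' @param voxel_size voxel edge, cm.
#' @param canopy_fraction height fraction defining "below the canopy".
#' @return The downsampled [point_cloud].
#' @export
voxel_filter_below_canopy <- function(cloud, voxel_size = 0.25,
                                      canopy_fraction = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"), voxel_size > 0,
            canopy_fraction > 0, canopy_fraction < 1)
  p <- cloud$points
  zr <- range(p[, 3])
  cut <- zr[1] + canopy_fraction * (zr[2] - zr[1])
  low <- p[, 3] < cut
  if (!any(low)) return(cloud)
  pl <- p[low, , drop = FALSE]
  mins <- apply(pl, 2, min)
  idx <- floor(sweep(pl, 2, mins) / voxel_size)
  g <- as.integer(interaction(idx[, 1], idx[, 2], idx[, 3], drop = TRUE))
  sums <- rowsum(pl, g)
  counts <- tabulate(g, nbins = max(g))[as.integer(rownames(sums))]
  centroids <- sums / counts
  point_cloud(rbind(p[!low, , drop = FALSE], unname(centroids)),
              cloud$sample_id)
}

#' Moving-least-squares surface smoothing
#'
#' Each point is projected onto the total-least-squares plane of its
#' neighbours within `radius` (degree-1 MLS), pushing stray "mixed" points
#' back onto the leaf surface. Point count is preserved; points with fewer
#' than 3 neighbours pass through unchanged.
#'
#' @param cloud a [point_cloud].
#' @param radius neighbourhood radius, cm.
#' @return The smoothed [point_cloud].
#' @export
mls_smooth <- function(cloud, radius = 1) {
  stopifnot(inherits(cloud, "point_cloud"), radius > 0)
  point_cloud(.mls_project(cloud$points, radius), cloud$sample_id)
}

#' Rebase the cloud so the plant bottom is z = 0
#' @param cloud a [point_cloud].
#' @return The shifted [point_cloud] (x, y unchanged, min z = 0).
#' @export
base_to_ground <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  p[, 3] <- p[, 3] - min(p[, 3])
  point_cloud(p, cloud$sample_id)
}

.grid_cells <- function(p, cell) {
  ix <- floor((p[, 1] - min(p[, 1])) / cell)
  iy <- floor((p[, 2] - min(p[, 2])) / cell)
  interaction(ix, iy, drop = TRUE)
}

#' Grid-based average plant height
#'
#' The x-y plane is partitioned into `cell` x `cell` squares anchored at
#' (min x, min y); the height is the mean over occupied cells of the per-cell
#' maximum z. Run [base_to_ground()] first so z is height above the plant
#' bottom.
#'
#' @param cloud a [point_cloud], based to ground.
#' @param cell grid cell edge, cm (default 0.5).
#' @return Average plant height, cm.
#' @export
grid_height <- function(cloud, cell = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"), cell > 0)
  key <- .grid_cells(cloud$points, cell)
  mean(tapply(cloud$points[, 3], key, max))
}

#' Grid-based canopy leaf area
#'
#' Number of occupied grid cells times the cell area.
#'
#' @inheritParams grid_height
#' @return Canopy leaf area, cm^2.
#' @export
canopy_leaf_area <- function(cloud, cell = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"), cell > 0)
  nlevels(.grid_cells(cloud$points, cell)) * cell^2
}

#' Convex-hull canopy volume
#'
#' Volume of the 3-D convex hull of the cloud, the proxy for the space the
#' canopy occupies.
#'
#' @param cloud a [point_cloud] with at least 4 non-coplanar points.
#' @return Hull volume, cm^3.
#' @export
convex_hull_volume <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  .convex_hull3d(cloud$points)$volume
}

# Full hull (volume + outward facet planes); used by the Monte-Carlo
# volume oracle in the test suite.
convex_hull3d <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  .convex_hull3d(cloud$points)
}

#' Structural trait extraction pipeline
#'
#' Applies the filter chain (outlier removal, sub-canopy voxel filter, MLS
#' smoothing, rebasing to ground) and then extracts plant height, canopy
#' leaf area and convex-hull volume.
#'
#' @param cloud a [point_cloud].
#' @param config a [filter_config()].
#' @param cell height/area grid cell, cm (default 0.5).
#' @return An object of class `structural_traits`: list with `sample_id`,
#'   `height` (cm), `canopy_leaf_area` (cm^2), `volume` (cm^3).
#' @export
extract_structural_traits <- function(cloud, config = filter_config(),
                                      cell = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "filter_config"))
  cloud <- remove_outliers(cloud, config$knn, config$std_multiplier)
  cloud <- voxel_filter_below_canopy(cloud, config$voxel_size,
                                     config$canopy_fraction)
  cloud <- mls_smooth(cloud, config$mls_radius)
  cloud <- base_to_ground(cloud)
  structure(list(sample_id = cloud$sample_id,
                 height = grid_height(cloud, cell),
                 canopy_leaf_area = canopy_leaf_area(cloud, cell),
                 volume = convex_hull_volume(cloud)),
            class = "structural_traits")
}

#' @export
print.structural_traits <- function(x, ...) {
  cat(sprintf(
    "<structural_traits> %s  height %.2f cm, leaf area %.1f cm^2, volume %.1f cm^3\n",
    x$sample_id, x$height, x$canopy_leaf_area, x$volume))
  invisible(x)
}
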