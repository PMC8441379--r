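#' Height metrics of a normalized plant cloud
#'
#' Maximum and mean point height plus height quantiles (linear interpolation
#' between closest order statistics, the common default rule).
#'
#' @param cloud a non-empty, height-normalized [point_cloud].
#' @param probs quantile probabilities; 0.99 is always included.
#' @return A list with `h_max`, `h_mean`, `h_99` and the named `quantiles`
#'   vector.
#' @export
height_metrics <- function(cloud, probs = c(seq(0.1, 0.9, 0.1), 0.99)) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("empty cloud")
  z <- cloud$coords[, 3]
  probs <- sort(unique(c(probs, 0.99)))
  q <- quantile(z, probs, type = 7, names = TRUE)
  list(h_max = max(z), h_mean = mean(z), h_99 = unname(q[probs == 0.99]),
       quantiles = q)
}

#' Crown size (maximum horizontal extent)
#'
#' The crown diameter: the maximum pairwise horizontal distance between
#' points, computed on the 2D convex hull of the horizontal projection so
#' the pairwise scan stays small.
#'
#' @param cloud a [point_cloud] with at least 2 points.
#' @return Crown size in m.
#' @export
crown_size <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 2) stop("crown size needs at least 2 points")
  xy <- cloud$coords[, 1:2, drop = FALSE]
  h <- unique(xy[chull(xy), , drop = FALSE])
  if (nrow(h) < 2) return(0)
  d <- as.matrix(dist(h))
  max(d)
}

#' Plant azimuth from the principal horizontal eigenvector
#'
#' The angle between the maximum eigenvector of the horizontally projected
#' point covariance and north (+y), clockwise, reported modulo 180 degrees
#' because the eigenvector sign is ambiguous. When the horizontal projection
#' is nearly isotropic (eigenvalue ratio < 1.05) the direction is poorly
#' defined and the result carries attribute `stable = FALSE` (with a
#' warning).
#'
#' @param cloud a [point_cloud] with at least 3 points.
#' @return Azimuth in degrees `[0, 180)` with attribute `stable`.
#' @export
plant_azimuth <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 3) stop("plant azimuth needs at least 3 points")
  xy <- cloud$coords[, 1:2, drop = FALSE]
  cv <- stats::cov(xy)
  if (!all(is.finite(cv)) || sum(diag(cv)) <= 0)
    stop("degenerate horizontal spread")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  az <- (atan2(v[1], v[2]) * 180 / pi) %% 180
  stable <- e$values[2] <= 0 || e$values[1] / e$values[2] >= 1.05
  if (!stable)
    warning("nearly isotropic horizontal projection; azimuth is unstable")
  structure(az, stable = stable)
}

#' Projected area by grid occupancy
#'
#' Rasterizes the horizontal projection onto a fixed grid (origin at 0, cell
#' `cell_size`) and returns occupied cells x cell area. Occupancy respects
#' leaf concavity, unlike a convex hull; the default 5 mm cell is about
#' twice the instrument resolution.
#'
#' @param cloud a non-empty [point_cloud].
#' @param cell_size raster cell size in m (> 0).
#' @return Projected area in m^2.
#' @export
projected_area <- function(cloud, cell_size = 0.005) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cell_size <= 0) stop("cell_size must be positive")
  if (n_points(cloud) == 0) return(0)
  ix <- floor(cloud$coords[, 1] / cell_size)
  iy <- floor(cloud$coords[, 2] / cell_size)
  ix <- ix - min(ix); iy <- iy - min(iy)
  length(unique(ix * (max(iy) + 1) + iy)) * cell_size^2
}

#' Convex-hull volume
#'
#' Volume of the 3D convex hull of the points (quickhull-style incremental
#' construction in C++). Degenerate (coplanar) input returns 0 with a
#' warning.
#'
#' @param cloud a [point_cloud] with at least 4 points.
#' @return Volume in m^3.
#' @export
hull_volume <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 4) stop("hull volume needs at least 4 points")
  v <- cpp_hull_volume(cloud$coords)
  if (v <= 0) {
    warning("degenerate (coplanar) cloud; hull volume is 0")
    return(0)
  }
  v
}

# Area of the 2D convex hull of the horizontal projection (shoelace).
footprint_area <- function(cloud) {
  xy <- unique(cloud$coords[, 1:2, drop = FALSE])
  if (nrow(xy) < 3) return(0)
  h <- xy[chull(xy), , drop = FALSE]
  n <- nrow(h)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
}

#' Projected area index
#'
#' Sum of per-leaf projected areas divided by the area of the 2D convex
#' hull of the whole plant's horizontal projection. Overlap between leaves
#' counts multiply in the numerator, so PAI can exceed 1.
#'
#' @param cloud a leaf-labeled [point_cloud] (labels >= 1 are leaves).
#' @param cell_size raster cell for the per-leaf projected areas.
#' @return PAI in m^2/m^2.
#' @export
pai <- function(cloud, cell_size = 0.005) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$label)) stop("pai needs leaf labels")
  fp <- footprint_area(cloud)
  if (fp <= 0) stop("zero horizontal footprint")
  leaves <- setdiff(unique(cloud$label), 0L)
  num <- 0
  for (k in leaves)
    num <- num + projected_area(pc_subset(cloud, which(cloud$label == k)),
                                cell_size)
  num / fp
}

#' Three-dimensional profile index
#'
#' Voxelizes the cloud and, over horizontal layers `i = 1..L` with filled
#' voxel counts `n_i`, returns `sum(n_i) / (L * max(n_i))`: 1 for a
#' vertically uniform occupancy profile, small when a single layer
#' dominates. A bounded substitute definition for the vertical-profile
#' fullness index.
#'
#' @param cloud a non-empty [point_cloud].
#' @param voxel voxel edge length in m (> 0, default 0.02).
#' @return Dimensionless value in `(0, 1]`.
#' @export
profile_index_3d <- function(cloud, voxel = 0.02) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (voxel <= 0) stop("voxel must be positive")
  if (n_points(cloud) == 0) stop("empty cloud")
  co <- cloud$coords
  zmin <- min(co[, 3])
  L <- max(1L, as.integer(ceiling((max(co[, 3]) - zmin) / voxel)))
  iz <- pmin(floor((co[, 3] - zmin) / voxel), L - 1)
  ix <- floor(co[, 1] / voxel); iy <- floor(co[, 2] / voxel)
  ix <- ix - min(ix); iy <- iy - min(iy)
  key <- (ix * (max(iy) + 1) + iy) * L + iz
  uk <- unique(key)
  layer <- uk %% L
  n_i <- tabulate(layer + 1, nbins = L)
  sum(n_i) / (L * max(n_i))
}

#' All nine plant-level structural traits
#'
#' Computes maximum height, mean height, the 99 % height quantile, crown
#' size, plant azimuth, projected leaf area (leaf-labeled points only, stem
#' excluded), convex-hull volume, projected area index and the 3D profile
#' index for one normalized single-plant cloud. Heights, crown and volume
#' use all plant points.
#'
#' @param cloud a normalized, labeled single-plant [point_cloud].
#' @param cell_size raster cell for PLA/PAI (m).
#' @param voxel voxel size for the 3D profile index (m).
#' @param probs height quantile probabilities.
#' @return A one-row data frame with the nine traits (and the height
#'   quantile vector as attribute `"quantiles"`).
#' @export
plant_traits_all <- function(cloud, cell_size = 0.005, voxel = 0.02,
                             probs = c(seq(0.1, 0.9, 0.1), 0.99)) {
  stopifnot(inherits(cloud, "point_cloud"))
  hm <- height_metrics(cloud, probs)
  leafy <- if (!is.null(cloud$label))
    pc_subset(cloud, which(cloud$label >= 1L)) else NULL
  pla <- if (!is.null(leafy) && n_points(leafy) > 0)
    projected_area(leafy, cell_size) else 0
  pai_v <- if (!is.null(leafy) && n_points(leafy) > 0)
    pai(cloud, cell_size) else 0
  vol <- if (n_points(cloud) >= 4) hull_volume(cloud) else 0
  out <- data.frame(
    h_max = hm$h_max, h_mean = hm$h_mean, h_99 = hm$h_99,
    crown_size = crown_size(cloud),
    azimuth_deg = as.numeric(plant_azimuth(cloud)),
    pla = pla, volume = vol, pai = pai_v,
    profile_3d = profile_index_3d(cloud, voxel))
  attr(out, "quantiles") <- hm$quantiles
  out
}
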