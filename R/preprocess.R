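#' Clip a point cloud to an axis-aligned horizontal box
#'
#' Keeps exactly the points with `x` in `[xmin, xmax]` and `y` in
#' `[ymin, ymax]` (closed intervals). Mirrors the manual clipping of a field
#' scan to the plot footprint.
#'
#' @param cloud a [point_cloud].
#' @param xmin,xmax,ymin,ymax box bounds in m, `xmin < xmax`, `ymin < ymax`.
#' @return The clipped [point_cloud], original point order preserved.
#' @export
clip_box <- function(cloud, xmin, xmax, ymin, ymax) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!(xmin < xmax) || !(ymin < ymax)) stop("degenerate clip box")
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]
  pc_subset(cloud, which(x >= xmin & x <= xmax & y >= ymin & y <= ymax))
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k_neighbors` nearest
#' neighbours and removes points whose mean distance exceeds the global mean
#' plus `n_sigma` standard deviations. This is the classic SOR filter used
#' by TLS processing software; parameters follow common practice and are
#' exposed because the field pipelines rarely document them.
#'
#' @param cloud a [point_cloud] with more than `k_neighbors` points.
#' @param k_neighbors number of nearest neighbours (default 20).
#' @param n_sigma rejection threshold in standard deviations (default 3).
#' @return The filtered [point_cloud], kept points in original order.
#' @export
remove_outliers <- function(cloud, k_neighbors = 20, n_sigma = 3) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n <= k_neighbors)
    stop("need more than k_neighbors = ", k_neighbors, " points (got ", n, ")")
  d <- cpp_knn_mean_dist(cloud$coords, as.integer(k_neighbors))
  keep <- d <= mean(d) + n_sigma * sd(d)
  pc_subset(cloud, which(keep))
}

#' Height normalization against a gridded digital terrain model
#'
#' Builds a DTM as the per-cell minimum z on a horizontal grid of
#' `cell_size`, infills empty cells from the nearest non-empty cell, smooths
#' with a 3 x 3 cell mean, and subtracts the bilinearly interpolated DTM
#' elevation from every point's z. Ground returns map to approximately zero;
#' x and y are untouched.
#'
#' @param cloud a non-empty [point_cloud].
#' @param cell_size DTM cell size in m (default 0.25).
#' @return The normalized [point_cloud], with the DTM attached as attribute
#'   `"dtm"` (a list with `origin`, `cell_size`, and elevation `grid`).
#' @export
normalize_height <- function(cloud, cell_size = 0.25) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("empty cloud")
  if (cell_size <= 0) stop("cell_size must be positive")
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]; z <- cloud$coords[, 3]
  x0 <- min(x); y0 <- min(y)
  ix <- pmin(floor((x - x0) / cell_size), ceiling((max(x) - x0) / cell_size) - 1)
  iy <- pmin(floor((y - y0) / cell_size), ceiling((max(y) - y0) / cell_size) - 1)
  ix <- pmax(ix, 0); iy <- pmax(iy, 0)
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  idx <- iy * nx + ix + 1
  minz <- tapply(z, idx, min)
  grid <- matrix(NA_real_, nrow = nx, ncol = ny)
  grid[as.integer(names(minz))] <- as.numeric(minz)

  # nearest-neighbour infill of empty cells (grids are small)
  if (anyNA(grid)) {
    filled <- which(!is.na(grid), arr.ind = TRUE)
    empty <- which(is.na(grid), arr.ind = TRUE)
    vals <- grid[!is.na(grid)]
    for (r in seq_len(nrow(empty))) {
      d2 <- (filled[, 1] - empty[r, 1])^2 + (filled[, 2] - empty[r, 2])^2
      grid[empty[r, 1], empty[r, 2]] <- vals[which.min(d2)]
    }
  }

  # 3 x 3 mean smoothing (edge cells average over available neighbours)
  sm <- grid
  if (nx > 1 || ny > 1) {
    acc <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
    for (di in -1:1) for (dj in -1:1) {
      si <- max(1, 1 + di):min(nx, nx + di)
      sj <- max(1, 1 + dj):min(ny, ny + dj)
      acc[si - di, sj - dj] <- acc[si - di, sj - dj] + grid[si, sj]
      cnt[si - di, sj - dj] <- cnt[si - di, sj - dj] + 1
    }
    sm <- acc / cnt
  }

  # bilinear interpolation between cell centers, clamped at the boundary
  gx <- pmin(pmax((x - x0) / cell_size - 0.5, 0), nx - 1)
  gy <- pmin(pmax((y - y0) / cell_size - 0.5, 0), ny - 1)
  i0 <- pmin(floor(gx), nx - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(gy), ny - 2); j0 <- pmax(j0, 0)
  if (nx == 1) i0 <- rep(0, length(gx))
  if (ny == 1) j0 <- rep(0, length(gy))
  fx <- gx - i0; fy <- gy - j0
  at <- function(i, j) sm[cbind(pmin(i, nx - 1) + 1, pmin(j, ny - 1) + 1)]
  dtm_z <- (1 - fx) * (1 - fy) * at(i0, j0) + fx * (1 - fy) * at(i0 + 1, j0) +
    (1 - fx) * fy * at(i0, j0 + 1) + fx * fy * at(i0 + 1, j0 + 1)
  out <- cloud
  out$coords[, 3] <- z - dtm_z
  attr(out, "dtm") <- list(origin = c(x0, y0), cell_size = cell_size,
                           grid = sm)
  out
}

#' Assign points to plants from the planting grid
#'
#' Stand-in for instance segmentation: each point is assigned to the nearest
#' planting-grid center within `max_radius` (horizontal distance); farther
#' points get plant id `NA`. Ties go to the center that appears earlier in
#' `grid_centers`. The default radius is half the 0.6 m planting interval.
#'
#' @param cloud a [point_cloud].
#' @param grid_centers matrix or data frame of planting positions, columns
#'   x, y in m.
#' @param max_radius maximum horizontal assignment distance in m.
#' @return The [point_cloud] with `plant` set (row index into
#'   `grid_centers`, `NA` when unassigned).
#' @export
cluster_plants <- function(cloud, grid_centers, max_radius = 0.3) {
  stopifnot(inherits(cloud, "point_cloud"))
  centers <- as.matrix(grid_centers)
  if (nrow(centers) == 0) stop("grid_centers must be non-empty")
  n <- n_points(cloud)
  if (n == 0) { cloud$plant <- integer(0); return(cloud) }
  best_d2 <- rep(Inf, n)
  best_id <- rep(NA_integer_, n)
  for (k in seq_len(nrow(centers))) {
    d2 <- (cloud$coords[, 1] - centers[k, 1])^2 +
      (cloud$coords[, 2] - centers[k, 2])^2
    upd <- d2 < best_d2   # strict: ties keep the earlier center
    best_d2[upd] <- d2[upd]
    best_id[upd] <- k
  }
  best_id[best_d2 > max_radius^2] <- NA_integer_
  cloud$plant <- best_id
  cloud
}

#' Standard preprocessing chain
#'
#' Applies the stages in their canonical order: clip to the plot box, remove
#' statistical outliers, normalize heights against the DTM, and cluster
#' points to planting positions.
#'
#' @inheritParams clip_box
#' @inheritParams remove_outliers
#' @inheritParams normalize_height
#' @inheritParams cluster_plants
#' @param box optional numeric vector `c(xmin, xmax, ymin, ymax)`; `NULL`
#'   skips clipping.
#' @return The preprocessed [point_cloud].
#' @export
preprocess_cloud <- function(cloud, box = NULL, grid_centers = NULL,
                             k_neighbors = 20, n_sigma = 3,
                             cell_size = 0.25, max_radius = 0.3) {
  if (!is.null(box)) cloud <- clip_box(cloud, box[1], box[2], box[3], box[4])
  cloud <- remove_outliers(cloud, k_neighbors, n_sigma)
  cloud <- normalize_height(cloud, cell_size)
  if (!is.null(grid_centers))
    cloud <- cluster_plants(cloud, grid_centers, max_radius)
  cloud
}
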