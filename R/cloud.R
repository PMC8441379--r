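#' Point cloud container
#'
#' A minimal container for a TLS point cloud: an N x 3 coordinate matrix in
#' meters plus optional per-point integer labels (0 = stem, k >= 1 = leaf k)
#' and plant ids. The coordinate convention throughout the package is z up,
#' +y = geographic north, +x = east; azimuths are measured clockwise from
#' north.
#'
#' @param coords numeric matrix (or data frame) with 3 columns x, y, z in m.
#' @param label optional integer vector, one per point (0 = stem, k = leaf k).
#' @param plant optional integer vector of plant ids, one per point.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(coords, label = NULL, plant = NULL) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 3)
  if (!is.matrix(coords) || ncol(coords) != 3L)
    stop("`coords` must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  if (nrow(coords) > 0 && !all(is.finite(coords)))
    stop("coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  n <- nrow(coords)
  if (!is.null(label)) {
    if (length(label) != n) stop("`label` length must match point count")
    label <- as.integer(label)
  }
  if (!is.null(plant)) {
    if (length(plant) != n) stop("`plant` length must match point count")
    plant <- as.integer(plant)
  }
  structure(list(coords = coords, label = label, plant = plant),
            class = "point_cloud")
}

#' @rdname point_cloud
#' @param x,cloud a `point_cloud`.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' @rdname point_cloud
#' @param ... ignored.
#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s%s>\n", n_points(x),
              if (!is.null(x$label)) ", labeled" else "",
              if (!is.null(x$plant)) ", plant ids" else ""))
  invisible(x)
}

# Subset a cloud by row index, keeping labels/plant ids aligned.
pc_subset <- function(cloud, idx) {
  point_cloud(cloud$coords[idx, , drop = FALSE],
              label = if (!is.null(cloud$label)) cloud$label[idx],
              plant = if (!is.null(cloud$plant)) cloud$plant[idx])
}

# Concatenate clouds; labels/plant ids are kept only if present everywhere.
pc_bind <- function(clouds) {
  clouds <- clouds[vapply(clouds, n_points, 0L) > 0]
  if (length(clouds) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  coords <- do.call(rbind, lapply(clouds, `[[`, "coords"))
  lab <- if (all(vapply(clouds, function(p) !is.null(p$label), TRUE)))
    unlist(lapply(clouds, `[[`, "label"))
  pl <- if (all(vapply(clouds, function(p) !is.null(p$plant), TRUE)))
    unlist(lapply(clouds, `[[`, "plant"))
  point_cloud(coords, label = lab, plant = pl)
}
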