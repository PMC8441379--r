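#' Extract a leaf midrib by principal-axis slicing
#'
#' Points are binned into `n_slices` equal-width slices along the leaf's
#' first principal eigenvector and slice centroids are computed. Several
#' corrections matter at realistic TLS densities (hundreds of points per
#' leaf):
#'
#' * the midrib curve is a count-weighted smoothing spline through the
#'   slice centroids (per coordinate, low fixed degrees of freedom — a
#'   midrib is a gentle curve), so centroid sampling noise does not zigzag
#'   the polyline and inflate the measured arc length;
#' * per-slice widths are estimated as `sqrt(12)` times the lateral point
#'   standard deviation (the minimum-variance scale estimate for a uniform
#'   spread) after deconvolving the sensor-noise variance, which is itself
#'   estimated from the blade's out-of-plane scatter; very sparse slices
#'   fall back to an order-statistic corrected range;
#' * the maximum width is read from a coarser width profile (bins of at
#'   least ~60 points) through a count-weighted quadratic peak fit, since
#'   the maximum of many noisy fine slices is badly biased upward and a
#'   single fine slice is too noisy;
#' * the curve is extended beyond the sampled extent to the zero-width
#'   intercept of the end width profile (tapering blades are never sampled
#'   all the way to the tip), clamped to at most 1.2 slices; non-tapering
#'   blades stop at the sampled extent.
#'
#' The base end is the end nearer the stem axis when `stem_xy` is given,
#' otherwise the lower end. Valid for leaves monotone along their principal
#' axis (the generator enforces this via the droop cap).
#'
#' @param leaf_cloud a [point_cloud] of one leaf.
#' @param n_slices number of slices (default 30).
#' @param stem_xy optional horizontal stem-axis position `c(x, y)` used to
#'   orient base vs. tip.
#' @return An object of class `leaf_midrib`: list with `vertices` (dense
#'   polyline sampled from the fitted curve, base first), `widths` (per
#'   non-empty slice, base first), `vertex_widths` (widths interpolated at
#'   the vertices), `max_width` (peak of the coarse width profile),
#'   `arc_length`, and `centroids` (the raw slice centroids).
#' @export
extract_midrib <- function(leaf_cloud, n_slices = 30, stem_xy = NULL) {
  stopifnot(inherits(leaf_cloud, "point_cloud"))
  co <- leaf_cloud$coords
  n <- nrow(co)
  if (n < 4) stop("too few points for midrib extraction")
  e <- eigen(stats::cov(co), symmetric = TRUE)
  e1 <- e$vectors[, 1]
  coordv <- as.vector(co %*% e1)
  if (diff(range(coordv)) <= 0) stop("degenerate leaf cloud")

  st <- slice_stats(co, coordv, n_slices, e1)
  if (length(st$tc) < 2) stop("fewer than 2 non-empty slices")

  # orient: base first (all coordinates are negated on flip)
  flip <- if (!is.null(stem_xy)) {
    d1 <- sum((st$cent[1, 1:2] - stem_xy)^2)
    d2 <- sum((st$cent[nrow(st$cent), 1:2] - stem_xy)^2)
    d2 < d1
  } else st$cent[nrow(st$cent), 3] < st$cent[1, 3]
  if (flip) {
    coordv <- -coordv
    st <- reverse_slices(st)
  }
  cent <- st$cent; tc <- st$tc; widths <- st$widths; counts <- st$counts
  m <- nrow(cent)
  lo <- min(coordv); hi <- max(coordv)
  h <- (hi - lo) / n_slices

  base <- taper_target(tc, widths, counts, lo, h)
  tipo <- taper_target(rev(-tc), rev(widths), rev(counts), -hi, h)
  t_base <- base$t; t_tip <- -tipo$t

  # midrib curve: count-weighted smoothing spline per coordinate
  n_grid <- 64L
  tgrid <- seq(t_base, t_tip, length.out = n_grid)
  vertices <- matrix(0, n_grid, 3)
  dfv <- max(4, min(8, m - 1))   # low df: the midrib is a gentle curve
  if (m >= 4 && length(unique(tc)) >= 4) {
    for (j in 1:3) {
      fit <- tryCatch(stats::smooth.spline(tc, cent[, j], w = counts,
                                           df = dfv),
                      error = function(e) NULL)
      if (is.null(fit)) { vertices <- NULL; break }
      vertices[, j] <- stats::predict(fit, tgrid)$y
    }
  } else vertices <- NULL
  if (is.null(vertices)) {            # degenerate: raw centroid polyline
    vertices <- cent
    tgrid <- tc
  }
  vertex_widths <- approx(c(t_base, tc, t_tip), c(base$w, widths, tipo$w),
                          xout = tgrid, rule = 2, ties = "ordered")$y

  # coarse width profile for the maximum: >= ~45 points per slice
  n_coarse <- max(6L, min(as.integer(n_slices), n %/% 60L))
  cs <- if (n_coarse < as.integer(n_slices))
    slice_stats(co, coordv, n_coarse, e1, sigma2 = st$sigma2) else st
  wmax_fit <- profile_peak(cs$tc, cs$widths, cs$counts, cs$h)

  seg <- sqrt(rowSums(diff(vertices)^2))
  structure(list(vertices = unname(vertices), widths = widths,
                 vertex_widths = vertex_widths, max_width = wmax_fit,
                 arc_length = sum(seg), centroids = unname(cent)),
            class = "leaf_midrib")
}

# Slice a cloud into equal-width bins along `coordv` and return per-slice
# centroids, counts and noise-deconvolved widths (ordered by coordinate;
# empty slices are dropped).
slice_stats <- function(co, coordv, nbins, e1, sigma2 = NULL) {
  rng <- range(coordv)
  h <- diff(rng) / nbins
  bin <- pmin(floor((coordv - rng[1]) / h), nbins - 1) + 1
  keep <- sort(unique(bin))
  cent <- t(vapply(keep, function(b) colMeans(co[bin == b, , drop = FALSE]),
                   numeric(3)))
  tc <- vapply(keep, function(b) mean(coordv[bin == b]), 0)
  ord <- order(tc)
  cent <- cent[ord, , drop = FALSE]
  tc <- tc[ord]
  binmap <- match(bin, keep[ord])
  m <- nrow(cent)
  tang <- rbind(cent[min(2, m), ] - cent[1, ],
                if (m > 2) cent[3:m, , drop = FALSE] -
                  cent[1:(m - 2), , drop = FALSE],
                if (m > 1) cent[m, ] - cent[m - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  counts <- tabulate(binmap, nbins = m)
  sd_lat <- sd_perp <- rng_lat <- numeric(m)
  for (i in seq_len(m)) {
    w <- c(tang[i, 2], -tang[i, 1], 0)     # cross(z, tangent), horizontal
    nw <- sqrt(sum(w^2))
    if (nw < 1e-8) {                        # near-vertical tangent: fall back
      w <- c(e1[2], -e1[1], 0); nw <- sqrt(sum(w^2))
      if (nw < 1e-8) w <- c(1, 0, 0) else w <- w / nw
    } else w <- w / nw
    nrm <- c(tang[i, 2] * w[3] - tang[i, 3] * w[2],
             tang[i, 3] * w[1] - tang[i, 1] * w[3],
             tang[i, 1] * w[2] - tang[i, 2] * w[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    pts_i <- co[binmap == i, , drop = FALSE]
    if (counts[i] >= 2) {
      pr <- pts_i %*% w
      sd_lat[i] <- sd(pr)
      sd_perp[i] <- sd(pts_i %*% nrm)       # out-of-plane scatter = noise
      rng_lat[i] <- diff(range(pr))
    }
  }
  if (is.null(sigma2)) {
    sigma2 <- stats::median(sd_perp[counts >= 8])^2
    if (!is.finite(sigma2)) sigma2 <- 0
  }
  # the (1 + 0.35/k) factor removes the O(1/k) Jensen bias of the sample
  # standard deviation for a uniform distribution
  widths <- ifelse(counts >= 8,
                   sqrt(12 * pmax(sd_lat^2 - sigma2, 0)) *
                     (1 + 0.35 / pmax(counts, 1)),
                   ifelse(counts >= 2,
                          rng_lat * (counts + 1) / pmax(counts - 1, 1), 0))
  list(cent = cent, tc = tc, widths = widths, counts = counts,
       sigma2 = sigma2, h = h)
}

reverse_slices <- function(st) {
  m <- nrow(st$cent)
  list(cent = st$cent[m:1, , drop = FALSE], tc = rev(-st$tc),
       widths = rev(st$widths), counts = rev(st$counts),
       sigma2 = st$sigma2, h = st$h)
}

# Peak of a width profile: count-weighted quadratic fit through the slices
# near the maximum (vertex of the parabola), falling back to the raw
# maximum when the fit is degenerate or the vertex falls outside the
# fitted window.
profile_peak <- function(tc, widths, counts, h) {
  wmax <- max(widths)
  near <- which(widths >= 0.6 * wmax)
  if (length(near) < 4) return(wmax)
  tt <- tc[near] - mean(tc[near])
  cf <- tryCatch(stats::lm.wfit(cbind(1, tt, tt^2), widths[near],
                                w = pmax(counts[near], 1))$coefficients,
                 error = function(e) rep(NA_real_, 3))
  if (!all(is.finite(cf)) || cf[3] >= 0) return(wmax)
  tv <- -cf[2] / (2 * cf[3])
  if (abs(tv) > max(abs(tt))) return(wmax)
  # -cf3 * h^2 / 24 undoes the within-bin averaging of a concave profile
  cf[1] + cf[2] * tv + cf[3] * tv^2 - cf[3] * h^2 / 24
}

# Where does this end of the blade really stop? Works in oriented
# coordinates with the end of interest at the smallest value, `lo` = the
# sampled extent. Count-weighted line fit of the end width profile; a
# tapering profile is extended to its zero-width intercept (at most 1.2
# slices beyond the data), a non-tapering one stops at the sampled extent.
taper_target <- function(tc, widths, counts, lo, h) {
  nf <- min(5L, length(tc))
  t_target <- lo
  w_target <- widths[1]
  if (nf >= 3) {
    tf <- tc[seq_len(nf)]
    wf <- widths[seq_len(nf)]
    kf <- pmax(counts[seq_len(nf)], 1)
    fit <- stats::lm.wfit(cbind(1, tf), wf, w = kf)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    w_lo <- a + b * lo
    if (is.finite(b) && b > 0 && w_lo < 0.35 * max(widths)) {
      t_target <- min(max(-a / b, lo - 1.2 * h), lo)
      w_target <- max(a + b * t_target, 0)
    } else {
      w_target <- max(min(w_lo, widths[1]), 0)
    }
  }
  list(t = t_target, w = w_target)
}

#' Leaf dimensions from a midrib
#'
#' Length is the midrib polyline arc length; mean width is the mean over
#' slice widths; maximum width is the peak of a local quadratic fit to the
#' width profile around its maximum (falling back to the raw slice maximum
#' for short profiles), which averages out per-slice sampling noise; area
#' is the strip (trapezoid) sum `sum((w_i + w_{i+1}) / 2 * segment_length)`
#' along the polyline using the per-vertex widths.
#'
#' @param midrib a [extract_midrib()] result.
#' @return A list with `length`, `max_width`, `mean_width`, `area`.
#' @export
leaf_dimensions <- function(midrib) {
  stopifnot(inherits(midrib, "leaf_midrib"))
  v <- midrib$vertices
  w_at <- midrib$vertex_widths
  seg <- sqrt(rowSums(diff(v)^2))
  area <- sum((w_at[-length(w_at)] + w_at[-1]) / 2 * seg)
  list(length = midrib$arc_length,
       max_width = midrib$max_width %||% max(midrib$widths),
       mean_width = mean(midrib$widths), area = area)
}

#' Leaf inclination and azimuth
#'
#' Inclination is the absolute elevation of the base-to-tip chord above
#' horizontal, in `[0, 90]` degrees. Azimuth is the clockwise angle from
#' north of the horizontal projection of the base-to-tip direction, in
#' `[0, 360)` (the principal-axis sign ambiguity is resolved base to tip).
#' A vertical chord leaves the azimuth undefined (`NA` with attribute
#' `defined = FALSE` and a warning).
#'
#' @param midrib a [extract_midrib()] result (already base-oriented).
#' @return A list with `inclination_deg` and `azimuth_deg`.
#' @export
leaf_angles <- function(midrib) {
  stopifnot(inherits(midrib, "leaf_midrib"))
  v <- midrib$vertices
  chord <- v[nrow(v), ] - v[1, ]
  horiz <- sqrt(chord[1]^2 + chord[2]^2)
  incl <- abs(atan2(chord[3], horiz)) * 180 / pi
  if (horiz < 1e-9) {
    warning("vertical chord: leaf azimuth undefined")
    az <- structure(NA_real_, defined = FALSE)
  } else {
    az <- structure((atan2(chord[1], chord[2]) * 180 / pi) %% 360,
                    defined = TRUE)
  }
  list(inclination_deg = incl, azimuth_deg = az)
}

#' All nine leaf-level structural traits
#'
#' Length, maximum width, mean width and area come from midrib slicing;
#' leaf height is the maximum point height (ground-normalized apex);
#' projected leaf length (PLL) is the arc length of the horizontally
#' projected midrib; projected leaf area (PLA) is the grid-occupancy
#' projected area of the leaf's points; inclination and azimuth come from
#' the base-to-tip chord.
#'
#' @param leaf_cloud a normalized, labeled single-leaf [point_cloud].
#' @param n_slices slices for midrib extraction.
#' @param cell_size raster cell for PLA (m).
#' @param stem_xy optional stem axis position for base/tip disambiguation.
#' @return A one-row data frame with the nine traits.
#' @export
leaf_traits_all <- function(leaf_cloud, n_slices = 30, cell_size = 0.005,
                            stem_xy = NULL) {
  mid <- extract_midrib(leaf_cloud, n_slices, stem_xy)
  dims <- leaf_dimensions(mid)
  ang <- leaf_angles(mid)
  vflat <- mid$vertices
  vflat[, 3] <- 0
  pll <- sum(sqrt(rowSums(diff(vflat)^2)))
  data.frame(length = dims$length, max_width = dims$max_width,
             mean_width = dims$mean_width,
             leaf_height = max(leaf_cloud$coords[, 3]),
             area = dims$area, pll = pll,
             pla = projected_area(leaf_cloud, cell_size),
             inclination_deg = ang$inclination_deg,
             azimuth_deg = as.numeric(ang$azimuth_deg))
}
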