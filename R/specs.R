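#' Parametric leaf specification
#'
#' A maize leaf is modelled as a ruled surface around a midrib. The midrib
#' runs from the attachment point toward the tip along a straight chord of
#' length `length` at elevation `inclination_deg` above horizontal and
#' azimuth `azimuth_deg` (clockwise from north), with a parabolic downward
#' deflection ("droop") that vanishes at both ends and reaches
#' `droop * length` at mid-span. The blade extends laterally (horizontal,
#' perpendicular to the chord) with the sine-arch width profile
#' `width(s) = max_width * sin(pi * s)`, `s` in `[0, 1]` along the midrib.
#' All true lengths, widths, angles and areas of this shape are available in
#' closed form, which is what makes downstream trait extraction testable.
#'
#' @param length base-to-tip chord length in m (> 0).
#' @param max_width maximum blade width in m (> 0).
#' @param attach_height attachment height on the stem in m.
#' @param inclination_deg chord elevation above horizontal, degrees in
#'   `[0, 90]`.
#' @param azimuth_deg base-to-tip azimuth, degrees clockwise from north in
#'   `[0, 360)`.
#' @param droop dimensionless parabolic deflection in `[0, 0.5]`; capped so
#'   the midrib stays monotone along its horizontal chord.
#' @return An object of class `leaf_spec`.
#' @export
leaf_spec <- function(length, max_width, attach_height, inclination_deg,
                      azimuth_deg, droop = 0.1) {
  if (length <= 0) stop("leaf length must be positive")
  if (max_width <= 0) stop("max_width must be positive")
  if (inclination_deg < 0 || inclination_deg > 90)
    stop("inclination_deg must be in [0, 90]")
  if (droop < 0 || droop > 0.5) stop("droop must be in [0, 0.5]")
  structure(list(length = length, max_width = max_width,
                 attach_height = attach_height,
                 inclination_deg = inclination_deg,
                 azimuth_deg = azimuth_deg %% 360, droop = droop),
            class = "leaf_spec")
}

#' Parametric plant specification
#'
#' A maize plant is a vertical stem cylinder plus an ordered list of
#' [leaf_spec] leaves attached along it.
#'
#' @param stem_height stem height in m (> 0).
#' @param stem_radius stem radius in m (default 0.015).
#' @param base_xy horizontal position of the stem axis, `c(x, y)` in m.
#' @param leaves list of [leaf_spec] objects; attachment heights must not
#'   exceed `stem_height`.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(stem_height, stem_radius = 0.015, base_xy = c(0, 0),
                       leaves = list()) {
  if (stem_height <= 0) stop("stem_height must be positive")
  if (stem_radius <= 0) stop("stem_radius must be positive")
  stopifnot(length(base_xy) == 2)
  for (lf in leaves) {
    if (!inherits(lf, "leaf_spec")) stop("leaves must be leaf_spec objects")
    if (lf$attach_height > stem_height + 1e-9)
      stop("leaf attach_height exceeds stem_height")
  }
  structure(list(stem_height = stem_height, stem_radius = stem_radius,
                 base_xy = as.numeric(base_xy), leaves = leaves),
            class = "plant_spec")
}

# Unit frame of a leaf: chord direction u, horizontal lateral direction w,
# and the 3D attachment point on the stem surface.
leaf_frame <- function(spec, base_xy = c(0, 0), stem_radius = 0) {
  th <- spec$azimuth_deg * pi / 180
  phi <- spec$inclination_deg * pi / 180
  h <- c(sin(th), cos(th), 0)                    # horizontal heading
  u <- c(sin(th) * cos(phi), cos(th) * cos(phi), sin(phi))
  w <- c(cos(th), -sin(th), 0)                   # horizontal, perp. to chord
  base <- c(base_xy[1], base_xy[2], spec$attach_height) + stem_radius * h
  list(u = u, w = w, base = base)
}

# Midrib points at parameters s in [0, 1] (matrix, one row per s).
midrib_points <- function(spec, s, base_xy = c(0, 0), stem_radius = 0) {
  fr <- leaf_frame(spec, base_xy, stem_radius)
  c0 <- spec$length
  out <- outer(s, fr$u) * c0
  out[, 3] <- out[, 3] - 4 * spec$droop * c0 * s * (1 - s)
  sweep(out, 2, fr$base, `+`)
}

# |dM/ds| of the midrib at s.
midrib_speed <- function(spec, s) {
  phi <- spec$inclination_deg * pi / 180
  spec$length * sqrt(cos(phi)^2 + (sin(phi) - 4 * spec$droop * (1 - 2 * s))^2)
}

#' Closed-form midrib arc length of a parametric leaf
#'
#' The midrib z-deflection is quadratic in the chord parameter, so the arc
#' length integral has the standard closed form for
#' `integral sqrt(a^2 + u^2)`. For `droop = 0` the arc length equals the
#' chord length.
#'
#' @param spec a [leaf_spec].
#' @return Arc length in m.
#' @export
midrib_arc_length <- function(spec) {
  d <- spec$droop
  phi <- spec$inclination_deg * pi / 180
  if (d == 0) return(spec$length)
  a <- cos(phi)
  u0 <- sin(phi) - 4 * d
  u1 <- sin(phi) + 4 * d
  F <- function(u) (u * sqrt(a^2 + u^2) + a^2 * asinh(u / a)) / 2
  spec$length * (F(u1) - F(u0)) / (8 * d)
}

#' True surface area of a parametric leaf
#'
#' `integral width(s) * |M'(s)| ds` evaluated by composite Simpson
#' quadrature (the width profile is analytic, the speed is smooth; 2001
#' nodes give far more accuracy than any tolerance used in tests). For a
#' flat leaf (`droop = 0`) this reduces to `(2/pi) * length * max_width`.
#'
#' @param spec a [leaf_spec].
#' @return Area in m^2.
#' @export
leaf_surface_area <- function(spec) {
  s <- seq(0, 1, length.out = 2001)
  f <- spec$max_width * sin(pi * s) * midrib_speed(spec, s)
  h <- s[2] - s[1]
  w <- rep(c(4, 2), length.out = length(s) - 2)
  sum(f[1], w * f[2:(length(s) - 1)], f[length(s)]) * h / 3
}

# True apex height of a leaf: the midrib z(s) is convex in s, so the
# maximum over the blade is attained at an endpoint.
leaf_apex_height <- function(spec) {
  phi <- spec$inclination_deg * pi / 180
  spec$attach_height + max(0, spec$length * sin(phi))
}

# True maximum plant height (stem apex vs. leaf apexes).
plant_apex_height <- function(spec) {
  apex <- spec$stem_height
  for (lf in spec$leaves) apex <- max(apex, leaf_apex_height(lf))
  apex
}

#' Random plant specification with field-plausible defaults
#'
#' Draws a mature ("plateau") maize plant: stem height around 2 m, 8-14
#' alternate (distichous) leaves with chord lengths 0.35-0.55 m, maximum
#' widths 0.05-0.09 m, inclinations 20-60 degrees and moderate droop. Leaf
#' lengths are capped at 0.55 m so neighbouring plants on a 0.6 m grid do
#' not overlap. `scale_sd` adds a per-plant multiplicative size jitter
#' (lognormal-free, truncated normal around 1) representing plant-to-plant
#' variability.
#'
#' @param n_leaves number of leaves; default drawn uniformly from 8:14
#'   (within the 5-15 range typical of maize).
#' @param stem_height nominal mature stem height in m.
#' @param base_xy horizontal plant position.
#' @param scale_sd standard deviation of the per-plant size factor
#'   (default 0.05, i.e. a 5 % coefficient of variation).
#' @param seed optional RNG seed (ambient stream when `NULL`).
#' @return A [plant_spec].
#' @export
random_plant_spec <- function(n_leaves = NULL, stem_height = 2,
                              base_xy = c(0, 0), scale_sd = 0.05,
                              seed = NULL) {
  with_seed(seed, {
    if (is.null(n_leaves)) n_leaves <- sample(8:14, 1)
    sc <- max(0.7, 1 + rnorm(1, 0, scale_sd))
    sh <- stem_height * sc
    base_az <- runif(1, 0, 360)
    leaves <- vector("list", n_leaves)
    attach <- seq(0.25, 0.95, length.out = n_leaves) * sh
    for (k in seq_len(n_leaves)) {
      az <- (base_az + (k %% 2) * 180 + rnorm(1, 0, 12)) %% 360
      leaves[[k]] <- leaf_spec(
        length = runif(1, 0.35, 0.55) * sc,
        max_width = runif(1, 0.05, 0.09) * sc,
        attach_height = attach[k],
        inclination_deg = runif(1, 20, 60),
        azimuth_deg = az,
        droop = runif(1, 0.05, 0.25))
    }
    plant_spec(stem_height = sh, base_xy = base_xy, leaves = leaves)
  })
}
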