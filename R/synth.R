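#' Sample a labeled point cloud from a parametric leaf
#'
#' Points are drawn uniformly over the leaf surface (the chord parameter is
#' drawn with density proportional to `width(s) * |M'(s)|`, the lateral
#' position uniformly across the local width) and perturbed by isotropic
#' Gaussian sensor noise. The point count is Poisson with mean
#' `density * area`, emulating TLS sampling of around 2 mm resolution.
#'
#' @param spec a [leaf_spec].
#' @param density sampling density in points/m^2 (> 0).
#' @param noise_sd isotropic Gaussian noise standard deviation in m
#'   (default 0.002, the instrument-scale 2 mm).
#' @param seed optional RNG seed; `NULL` uses the ambient stream.
#' @param label integer label stored on every point (the leaf index).
#' @param base_xy,stem_radius attachment geometry when the leaf belongs to a
#'   plant.
#' @return A labeled [point_cloud].
#' @export
sample_leaf <- function(spec, density, noise_sd = 0.002, seed = NULL,
                        label = 1L, base_xy = c(0, 0), stem_radius = 0) {
  stopifnot(inherits(spec, "leaf_spec"))
  if (density <= 0) stop("density must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    sgrid <- seq(0, 1, length.out = 4097)
    f <- spec$max_width * sin(pi * sgrid) * midrib_speed(spec, sgrid)
    h <- sgrid[2] - sgrid[1]
    area <- sum((f[-1] + f[-length(f)]) / 2) * h
    n <- rpois(1, density * area)
    if (n == 0)
      return(point_cloud(matrix(numeric(0), ncol = 3),
                         label = integer(0)))
    cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * h))
    s <- approx(cdf / cdf[length(cdf)], sgrid, runif(n), ties = "ordered")$y
    v <- runif(n, -1, 1)
    fr <- leaf_frame(spec, base_xy, stem_radius)
    pts <- midrib_points(spec, s, base_xy, stem_radius) +
      (v * spec$max_width * sin(pi * s) / 2) %o% fr$w
    if (noise_sd > 0)
      pts <- pts + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
    point_cloud(pts, label = rep(as.integer(label), n))
  })
}

#' Sample a labeled point cloud from a parametric plant
#'
#' The stem cylinder's lateral surface is sampled with label 0; each leaf is
#' sampled with [sample_leaf()] and labels `1..K`. For a fixed seed the
#' output is bit-identical across calls.
#'
#' @param spec a [plant_spec].
#' @param density points/m^2.
#' @param noise_sd Gaussian noise sd in m.
#' @param seed optional RNG seed.
#' @param plant_id plant id stored on every point.
#' @return A labeled [point_cloud] with plant ids.
#' @export
sample_plant <- function(spec, density, noise_sd = 0.002, seed = NULL,
                         plant_id = 1L) {
  stopifnot(inherits(spec, "plant_spec"))
  if (density <= 0) stop("density must be positive")
  with_seed(seed, {
    area <- 2 * pi * spec$stem_radius * spec$stem_height
    n <- rpois(1, density * area)
    th <- runif(n, 0, 2 * pi)
    stem <- cbind(spec$base_xy[1] + spec$stem_radius * cos(th),
                  spec$base_xy[2] + spec$stem_radius * sin(th),
                  runif(n, 0, spec$stem_height))
    if (n > 0 && noise_sd > 0)
      stem <- stem + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
    parts <- list(point_cloud(stem, label = rep(0L, n)))
    for (k in seq_along(spec$leaves))
      parts[[k + 1]] <- sample_leaf(spec$leaves[[k]], density, noise_sd,
                                    seed = NULL, label = k,
                                    base_xy = spec$base_xy,
                                    stem_radius = spec$stem_radius)
    out <- pc_bind(parts)
    out$plant <- rep(as.integer(plant_id), n_points(out))
    out
  })
}

#' Logistic seasonal growth model
#'
#' Each governed dimension is multiplied by the logistic factor
#' `L / (1 + exp(-r * (t - t_mid)))`, `t` in days after planting. With the
#' default `L = 1` the base specification holds the mature (plateau) values.
#' Defaults place the inflection around day 68 with `r = 0.12`/day, so
#' growth is strong across the jointing, bell-mouthed and heading stages
#' (days 67/78/98) and has plateaued by maturity (day 112).
#'
#' @param stem,leaf_length,leaf_width lists with elements `L` (plateau
#'   multiplier), `r` (rate, 1/day) and `t_mid` (inflection day).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(stem = list(L = 1, r = 0.12, t_mid = 68),
                         leaf_length = list(L = 1, r = 0.14, t_mid = 65),
                         leaf_width = list(L = 1, r = 0.14, t_mid = 65)) {
  structure(list(stem = stem, leaf_length = leaf_length,
                 leaf_width = leaf_width), class = "growth_model")
}

logistic_factor <- function(p, t) p$L / (1 + exp(-p$r * (t - p$t_mid)))

#' Apply seasonal growth to a plant specification
#'
#' Scales stem height and leaf attachment heights by the stem growth factor,
#' leaf chord lengths by the leaf-length factor and leaf widths by the
#' leaf-width factor, all evaluated at `t_days`. Monotone non-decreasing in
#' `t_days`.
#'
#' @param base a [plant_spec] holding mature (plateau) values when `L = 1`.
#' @param growth a [growth_model].
#' @param t_days days after planting (>= 0).
#' @return A [plant_spec] at age `t_days`.
#' @export
grow_spec <- function(base, growth, t_days) {
  stopifnot(inherits(base, "plant_spec"), inherits(growth, "growth_model"))
  if (t_days < 0) stop("t_days must be non-negative")
  gs <- logistic_factor(growth$stem, t_days)
  gl <- logistic_factor(growth$leaf_length, t_days)
  gw <- logistic_factor(growth$leaf_width, t_days)
  leaves <- lapply(base$leaves, function(lf)
    leaf_spec(length = lf$length * gl, max_width = lf$max_width * gw,
              attach_height = lf$attach_height * gs,
              inclination_deg = lf$inclination_deg,
              azimuth_deg = lf$azimuth_deg, droop = lf$droop))
  plant_spec(stem_height = base$stem_height * gs,
             stem_radius = base$stem_radius, base_xy = base$base_xy,
             leaves = leaves)
}

#' Sinusoidal circadian modulation model
#'
#' A 24 h sinusoid per governed trait family: modulated value =
#' base + amplitude * sin(2 * pi * (clock - phase) / 24), so the field peaks
#' at `phase + 6` h and its mean over a uniformly sampled full cycle equals
#' the base value. Amplitudes are in trait units (m for heights, degrees for
#' angles). Defaults: 2 cm height movement, 3 degrees of inclination and 1
#' degree of azimuth, peaking in the early afternoon.
#'
#' @param amp_height,amp_inclination,amp_azimuth amplitudes (m, deg, deg),
#'   all >= 0.
#' @param phase_height,phase_inclination,phase_azimuth phases in clock hours.
#' @return An object of class `circadian_model`.
#' @export
circadian_model <- function(amp_height = 0.02, amp_inclination = 3,
                            amp_azimuth = 1, phase_height = 8,
                            phase_inclination = 8, phase_azimuth = 8) {
  if (amp_height < 0 || amp_inclination < 0 || amp_azimuth < 0)
    stop("amplitudes must be non-negative")
  structure(list(amp_height = amp_height, amp_inclination = amp_inclination,
                 amp_azimuth = amp_azimuth, phase_height = phase_height,
                 phase_inclination = phase_inclination,
                 phase_azimuth = phase_azimuth), class = "circadian_model")
}

#' Apply circadian modulation to a plant specification at a clock time
#'
#' @param spec a [plant_spec].
#' @param circ a [circadian_model].
#' @param clock_h clock time in hours, `[0, 24)`.
#' @return The modulated [plant_spec].
#' @export
modulate_spec <- function(spec, circ, clock_h) {
  stopifnot(inherits(spec, "plant_spec"), inherits(circ, "circadian_model"))
  if (clock_h < 0 || clock_h >= 24) stop("clock_h must be in [0, 24)")
  wave <- function(amp, phase) amp * sin(2 * pi * (clock_h - phase) / 24)
  dh <- wave(circ$amp_height, circ$phase_height)
  di <- wave(circ$amp_inclination, circ$phase_inclination)
  da <- wave(circ$amp_azimuth, circ$phase_azimuth)
  sh <- max(spec$stem_height + dh, 1e-6)
  leaves <- lapply(spec$leaves, function(lf)
    leaf_spec(length = lf$length, max_width = lf$max_width,
              attach_height = min(max(lf$attach_height + dh, 0), sh),
              inclination_deg = min(max(lf$inclination_deg + di, 0), 90),
              azimuth_deg = (lf$azimuth_deg + da) %% 360,
              droop = lf$droop))
  plant_spec(stem_height = sh, stem_radius = spec$stem_radius,
             base_xy = spec$base_xy, leaves = leaves)
}

truth_rows <- function(spec, moment, t_days, clock_h, plant_id) {
  leaf_df <- if (length(spec$leaves)) do.call(rbind, lapply(
    seq_along(spec$leaves), function(k) {
      lf <- spec$leaves[[k]]
      data.frame(moment = moment, t_days = t_days, clock_h = clock_h,
                 plant = plant_id, leaf = k, length = lf$length,
                 arc_length = midrib_arc_length(lf),
                 max_width = lf$max_width,
                 area = leaf_surface_area(lf),
                 attach_height = lf$attach_height,
                 apex_height = leaf_apex_height(lf),
                 inclination_deg = lf$inclination_deg,
                 azimuth_deg = lf$azimuth_deg, droop = lf$droop,
                 stem_height = spec$stem_height,
                 h_max = plant_apex_height(spec))
    })) else NULL
  leaf_df
}

#' Simulate a time series of labeled plant clouds with ground truth
#'
#' For each observation moment the base specification is grown to the
#' moment's age, circadian-modulated at the moment's clock time, and
#' sampled. Returns one cloud per moment plus a truth table holding the
#' generating values for every (moment, plant, leaf).
#'
#' @param base a [plant_spec] or list of them (one per plant).
#' @param growth a [growth_model] (or `NULL` for no seasonal growth).
#' @param circ a [circadian_model] (or `NULL` for no circadian modulation).
#' @param moments `POSIXct` vector of observation times, strictly
#'   increasing.
#' @param planting `POSIXct` planting time (defines days after planting).
#' @param density points/m^2.
#' @param noise_sd sensor noise sd in m.
#' @param seed RNG seed for the whole series.
#' @return A list with elements `clouds` (list of [point_cloud], one per
#'   moment, multi-plant clouds carry plant ids) and `truth` (data frame).
#' @export
simulate_series <- function(base, growth = growth_model(),
                            circ = circadian_model(), moments, planting,
                            density = 5e4, noise_sd = 0.002, seed = 1) {
  if (inherits(base, "plant_spec")) base <- list(base)
  moments <- as.POSIXct(moments)
  if (length(moments) > 1 && any(diff(as.numeric(moments)) <= 0))
    stop("moments must be strictly increasing")
  with_seed(seed, {
    clouds <- vector("list", length(moments))
    truth <- list()
    for (m in seq_along(moments)) {
      t_days <- as.numeric(difftime(moments[m], planting, units = "days"))
      if (t_days < 0) stop("moment precedes planting")
      clock_h <- clock_hour(moments[m])
      per_plant <- vector("list", length(base))
      for (p in seq_along(base)) {
        spec_t <- base[[p]]
        if (!is.null(growth)) spec_t <- grow_spec(spec_t, growth, t_days)
        if (!is.null(circ)) spec_t <- modulate_spec(spec_t, circ, clock_h)
        per_plant[[p]] <- sample_plant(spec_t, density, noise_sd,
                                       seed = NULL, plant_id = p)
        tr <- truth_rows(spec_t, moments[m], t_days, clock_h, p)
        if (!is.null(tr)) truth[[length(truth) + 1]] <- tr
      }
      clouds[[m]] <- pc_bind(per_plant)
    }
    list(clouds = clouds,
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  })
}

clock_hour <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Diurnal environment model
#'
#' PAR follows a half-sine between sunrise and sunset (zero at night),
#' temperature a 24 h sinusoid between `t_min` and `t_max` peaking at
#' `t_peak_h`, and relative humidity is anti-phase to temperature between
#' `rh_min` and `rh_max`. Defaults describe a clear mid-June day at the
#' study latitude (sunrise 04:46, sunset 19:46, PAR peak 1500
#' umol m^-2 s^-1, 18-30 degC, 40-80 % RH).
#'
#' @param par_peak peak PAR in umol m^-2 s^-1.
#' @param t_min,t_max daily temperature range in degC.
#' @param t_peak_h clock hour of the temperature peak.
#' @param rh_min,rh_max relative humidity range in percent.
#' @param sunrise,sunset clock hours of sunrise and sunset.
#' @return An object of class `env_model`.
#' @export
env_model <- function(par_peak = 1500, t_min = 18, t_max = 30, t_peak_h = 14,
                      rh_min = 40, rh_max = 80,
                      sunrise = 4 + 46 / 60, sunset = 19 + 46 / 60) {
  if (rh_min < 0 || rh_max > 100 || rh_min > rh_max)
    stop("RH range must satisfy 0 <= rh_min <= rh_max <= 100")
  if (par_peak < 0) stop("par_peak must be non-negative")
  if (!(sunrise < sunset)) stop("sunrise must precede sunset")
  structure(list(par_peak = par_peak, t_min = t_min, t_max = t_max,
                 t_peak_h = t_peak_h, rh_min = rh_min, rh_max = rh_max,
                 sunrise = sunrise, sunset = sunset), class = "env_model")
}

env_at <- function(env, clock_h) {
  day <- clock_h > env$sunrise & clock_h < env$sunset
  par <- ifelse(day, env$par_peak *
                  sin(pi * (clock_h - env$sunrise) /
                        (env$sunset - env$sunrise)), 0)
  par <- pmax(par, 0)
  tmid <- (env$t_min + env$t_max) / 2
  tamp <- (env$t_max - env$t_min) / 2
  temp <- tmid + tamp * cos(2 * pi * (clock_h - env$t_peak_h) / 24)
  rh <- env$rh_max - (env$rh_max - env$rh_min) *
    (temp - env$t_min) / max(env$t_max - env$t_min, 1e-12)
  data.frame(par = par, temperature = temp, rh = rh)
}

#' Simulate an environmental record at fixed cadence
#'
#' @param env an [env_model].
#' @param start,end `POSIXct` bounds, `start < end`.
#' @param step_min cadence in minutes (default 30, the half-hourly logger).
#' @param noise_sd optional named vector of Gaussian measurement noise sds
#'   for `par`, `temperature`, `rh` (default all 0). PAR is clamped at 0 and
#'   RH to `[0, 100]` after noising.
#' @param seed optional RNG seed.
#' @return A data frame of class `env_series` with columns `time`, `par`,
#'   `temperature`, `rh`.
#' @export
simulate_env <- function(env, start, end, step_min = 30,
                         noise_sd = c(par = 0, temperature = 0, rh = 0),
                         seed = NULL) {
  stopifnot(inherits(env, "env_model"))
  start <- as.POSIXct(start); end <- as.POSIXct(end)
  if (!(start < end)) stop("start must precede end")
  if (step_min <= 0) stop("step_min must be positive")
  times <- seq(start, end, by = step_min * 60)
  vals <- env_at(env, clock_hour(times))
  with_seed(seed, {
    ns <- function(k) if (!is.na(noise_sd[k]) && noise_sd[k] > 0)
      rnorm(nrow(vals), 0, noise_sd[k]) else 0
    vals$par <- pmax(vals$par + ns("par"), 0)
    vals$temperature <- vals$temperature + ns("temperature")
    vals$rh <- pmin(pmax(vals$rh + ns("rh"), 0), 100)
    structure(data.frame(time = times, vals),
              class = c("env_series", "data.frame"))
  })
}

#' The published observation schedules
#'
#' Convenience constructors for the two circadian scanning schedules (16
#' moments from one sunset to past the next under standard conditions; 14
#' moments under cold stress) and the four seasonal stage days (67, 78, 98
#' and 112 days after planting: jointing, bell-mouthed, heading, maturity).
#'
#' @param planting `POSIXct` planting time (used by `stage_moments`).
#' @return `POSIXct` vector (`circadian_moments_*`) or numeric days
#'   (`stage_days`).
#' @export
circadian_moments_standard <- function() {
  d1 <- c("19:49", "21:48", "23:48")
  d2 <- c("01:48", "03:48", "04:48", "06:48", "08:48", "10:48", "12:00",
          "12:48", "14:48", "16:48", "18:48", "19:48", "21:48")
  as.POSIXct(c(paste("2019-06-22", d1), paste("2019-06-23", d2)), tz = "UTC")
}

#' @rdname circadian_moments_standard
#' @export
circadian_moments_stress <- function() {
  d1 <- c("18:00", "20:00", "22:00", "22:30")
  d2 <- c("00:00", "02:00", "04:00", "06:00", "08:00", "10:00", "12:00",
          "14:00", "16:00", "18:00")
  as.POSIXct(c(paste("2019-11-09", d1), paste("2019-11-10", d2)), tz = "UTC")
}

#' @rdname circadian_moments_standard
#' @export
stage_days <- function() c(67, 78, 98, 112)

#' @rdname circadian_moments_standard
#' @export
stage_moments <- function(planting = as.POSIXct("2019-03-25 12:00:00",
                                                tz = "UTC")) {
  planting + stage_days() * 86400
}
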