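planting <- as.POSIXct("2019-03-25 12:00:00", tz = "UTC")

test_that("a horizontal flat leaf samples at its attachment height", {
  sp <- leaf_spec(0.4, 0.08, attach_height = 1, inclination_deg = 0,
                  azimuth_deg = 90, droop = 0)
  cl <- sample_leaf(sp, 5e4, noise_sd = 0, seed = 1)
  expect_true(all(abs(cl$coords[, 3] - 1) < 1e-12))
  expect_true(all(cl$label == 1L))
})

test_that("the sampled chord azimuth matches the specification", {
  sp <- leaf_spec(0.5, 0.08, attach_height = 1, inclination_deg = 20,
                  azimuth_deg = 37, droop = 0)
  cl <- sample_leaf(sp, 1e5, noise_sd = 0, seed = 2)
  # oracle: arctangent of the displacement from base to the tip-end centroid
  fr <- tlsrhythm:::leaf_frame(sp)
  t_along <- (cl$coords %*% fr$u)
  tip <- colMeans(cl$coords[t_along > quantile(t_along, 0.9), , drop = FALSE])
  d <- tip - fr$base
  az <- (atan2(d[1], d[2]) * 180 / pi) %% 360
  expect_lt(abs(az - 37), 0.5)
})

test_that("point counts are Poisson around density times area", {
  sp <- leaf_spec(0.5, 0.08, 1, 30, 10, droop = 0.1)
  area <- leaf_surface_area(sp)
  counts <- vapply(1:20, function(s)
    n_points(sample_leaf(sp, 1e5, 0.002, seed = s)), 0L)
  expect_lt(abs(mean(counts) - 1e5 * area), 3 * sqrt(1e5 * area))
})

test_that("closed-form arc length matches fine quadrature", {
  for (d in c(0, 0.1, 0.3, 0.5)) {
    sp <- leaf_spec(0.5, 0.08, 1, 35, 210, droop = d)
    s <- seq(0, 1, length.out = 20001)
    mids <- (s[-1] + s[-length(s)]) / 2
    quad <- sum(tlsrhythm:::midrib_speed(sp, mids)) * (s[2] - s[1])
    expect_equal(midrib_arc_length(sp), quad, tolerance = 1e-8)
  }
})

test_that("sample_plant is deterministic and labels stem + leaves", {
  sp <- random_plant_spec(n_leaves = 8, seed = 3)
  a <- sample_plant(sp, 2e4, 0.002, seed = 7)
  b <- sample_plant(sp, 2e4, 0.002, seed = 7)
  expect_identical(a$coords, b$coords)
  expect_identical(a$label, b$label)
  expect_setequal(unique(a$label), 0:8)
  # stem-only plant: max z equals stem height exactly without noise
  stem <- plant_spec(stem_height = 2, leaves = list())
  cl <- sample_plant(stem, 5e4, noise_sd = 0, seed = 4)
  expect_true(all(cl$label == 0L))
  expect_lt(abs(max(cl$coords[, 3]) - 2), 1e-3)
  expect_lte(max(cl$coords[, 3]), 2 + 1e-12)
})

test_that("invalid generator inputs are rejected", {
  expect_error(leaf_spec(0.5, 0.08, 1, 30, 0, droop = 0.6), "droop")
  expect_error(leaf_spec(-1, 0.08, 1, 30, 0), "positive")
  expect_error(sample_leaf(leaf_spec(0.5, 0.08, 1, 30, 0), density = 0),
               "density")
  expect_error(plant_spec(2, leaves = list(
    leaf_spec(0.5, 0.08, attach_height = 3, 30, 0))), "attach_height")
})

test_that("logistic growth hits its plateau, midpoint and monotonicity", {
  base <- random_plant_spec(n_leaves = 6, seed = 5)
  g <- growth_model()
  late <- grow_spec(base, g, 300)
  expect_equal(late$stem_height, base$stem_height, tolerance = 0.01)
  mid <- grow_spec(base, g, g$stem$t_mid)
  expect_equal(mid$stem_height, base$stem_height / 2, tolerance = 1e-9)
  hs <- vapply(seq(0, 200, by = 5),
               function(t) grow_spec(base, g, t)$stem_height, 0)
  expect_true(all(diff(hs) >= -1e-12))
  lens <- vapply(seq(0, 200, by = 5),
                 function(t) grow_spec(base, g, t)$leaves[[1]]$length, 0)
  expect_true(all(diff(lens) >= -1e-12))
  expect_error(grow_spec(base, g, -1), "non-negative")
})

test_that("circadian modulation is a pure 24 h sinusoid", {
  base <- random_plant_spec(n_leaves = 4, seed = 6)
  zero <- circadian_model(amp_height = 0, amp_inclination = 0,
                          amp_azimuth = 0)
  expect_equal(modulate_spec(base, zero, 13)$stem_height, base$stem_height)
  circ <- circadian_model(amp_height = 0.05, phase_height = 3)
  peak <- modulate_spec(base, circ, 9)        # phase + 6 h = sine maximum
  expect_equal(peak$stem_height, base$stem_height + 0.05, tolerance = 1e-12)
  # 24 hourly samples average back to the base value
  hs <- vapply(0:23, function(h)
    modulate_spec(base, circ, h)$stem_height, 0)
  expect_equal(mean(hs), base$stem_height, tolerance = 1e-9)
  expect_error(modulate_spec(base, circ, 24), "clock_h")
})

test_that("simulate_series follows the published observation schedules", {
  base <- random_plant_spec(n_leaves = 5, seed = 8)
  m16 <- circadian_moments_standard()
  expect_length(m16, 16)
  sim <- simulate_series(base, growth_model(), circadian_model(), m16,
                         planting, density = 5e3, seed = 9)
  expect_length(sim$clouds, 16)
  expect_equal(nrow(sim$truth), 16 * 5)
  expect_length(circadian_moments_stress(), 14)

  stages <- planting + stage_days() * 86400
  sim4 <- simulate_series(base, growth_model(), NULL, stages, planting,
                          density = 5e3, seed = 10)
  expect_length(sim4$clouds, 4)
  stem_truth <- unique(sim4$truth[, c("moment", "stem_height")])
  expect_true(all(diff(stem_truth$stem_height) >= 0))
  maxz <- vapply(sim4$clouds, function(cl) max(cl$coords[, 3]), 0)
  expect_true(all(diff(maxz) >= -0.02))
})

test_that("a single plateau moment reproduces sample_plant exactly", {
  base <- random_plant_spec(n_leaves = 5, seed = 11)
  moment <- planting + 400 * 86400
  sim <- simulate_series(base, growth_model(), NULL, moment, planting,
                         density = 5e3, noise_sd = 0.002, seed = 12)
  spec_t <- grow_spec(base, growth_model(),
                      as.numeric(difftime(moment, planting, units = "days")))
  direct <- sample_plant(spec_t, 5e3, 0.002, seed = 12)
  expect_equal(sim$clouds[[1]]$coords, direct$coords)
})

test_that("simulated environment has the stated cadence and night zeros", {
  env <- env_model()
  day <- as.POSIXct("2019-06-22 00:00:00", tz = "UTC")
  es <- simulate_env(env, day, day + 24 * 3600, step_min = 30)
  expect_equal(nrow(es), 49)
  expect_true(all(es$par[tlsrhythm:::clock_hour(es$time) < 4.5] == 0))
  at_peak <- es$temperature[tlsrhythm:::clock_hour(es$time) == 14]
  expect_equal(at_peak, 30, tolerance = 1e-9)
  expect_true(all(es$rh >= 0 & es$rh <= 100))
  expect_error(simulate_env(env, day, day), "precede")
  expect_error(simulate_env(env, day, day + 3600, step_min = 0), "positive")
})

test_that("series moments must increase and precede-planting is caught", {
  base <- random_plant_spec(n_leaves = 3, seed = 13)
  mm <- planting + c(86400, 86400)
  expect_error(simulate_series(base, NULL, NULL, mm, planting,
                               density = 1e3), "increasing")
  expect_error(simulate_series(base, NULL, NULL, planting - 86400, planting,
                               density = 1e3), "precedes")
})
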