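test_that("height metrics match order-statistic oracles", {
  cl <- point_cloud(cbind(0, 0, c(0, 1, 2)))
  hm <- height_metrics(cl)
  expect_equal(hm$h_max, 2)
  expect_equal(hm$h_mean, 1)
  set.seed(14)
  u <- point_cloud(cbind(runif(1e5), runif(1e5), runif(1e5)))
  expect_lt(abs(height_metrics(u)$h_99 - 0.99), 0.005)
  one <- height_metrics(point_cloud(cbind(0, 0, 0.7)))
  expect_equal(one$h_max, one$h_mean)
  expect_equal(one$h_max, one$h_99)
  expect_error(height_metrics(point_cloud(matrix(numeric(0), ncol = 3))),
               "empty")
})

test_that("crown size equals the maximum pairwise horizontal distance", {
  two <- point_cloud(rbind(c(0, 0, 0), c(0.8, 0, 5)))
  expect_equal(crown_size(two), 0.8)
  set.seed(15)
  th <- runif(20000, 0, 2 * pi); r <- sqrt(runif(20000)) * 0.5
  disc <- point_cloud(cbind(r * cos(th), r * sin(th), runif(20000)))
  expect_equal(crown_size(disc), 1, tolerance = 0.01)
  # oracle: brute-force pairwise scan on a subsample never exceeds it
  sub <- disc$coords[sample(20000, 1000), 1:2]
  expect_gte(crown_size(disc) + 1e-9, max(dist(sub)))
  # invariant under rotation about z
  expect_equal(crown_size(rotate_z(disc, 33)), crown_size(disc),
               tolerance = 1e-9)
  expect_error(crown_size(point_cloud(cbind(0, 0, 0))), "2 points")
})

test_that("plant azimuth is the principal horizontal direction", {
  line <- point_cloud(cbind(seq(-1, 1, 0.01), rnorm(201, 0, 1e-4),
                            runif(201)))
  expect_equal(as.numeric(plant_azimuth(line)), 90, tolerance = 0.1)
  # equivariance modulo 180
  rot <- rotate_z(line, 30)
  expect_equal(as.numeric(plant_azimuth(rot)),
               (as.numeric(plant_azimuth(line)) + 30) %% 180,
               tolerance = 1e-6)
  # synthetic plant with one dominant leaf pair at 37/217 degrees
  leaves <- list(
    leaf_spec(0.55, 0.09, 0.8, 30, 37, droop = 0.1),
    leaf_spec(0.55, 0.09, 1.0, 30, 217, droop = 0.1),
    leaf_spec(0.2, 0.03, 1.2, 30, 127, droop = 0.1))
  pl <- plant_spec(2, leaves = leaves)
  cl <- sample_plant(pl, 5e4, 0.002, seed = 16)
  expect_lt(abs(as.numeric(plant_azimuth(cl)) - 37), 1)
  # isotropic projection flags instability
  set.seed(17)
  iso <- point_cloud(cbind(rnorm(5000), rnorm(5000), runif(5000)))
  expect_warning(res <- plant_azimuth(iso), "unstable")
  expect_false(attr(res, "stable"))
})

test_that("projected area approximates analytic areas of planar patches", {
  set.seed(18)
  sq <- point_cloud(cbind(runif(4e5), runif(4e5), 0))
  expect_equal(projected_area(sq, 0.005), 1, tolerance = 0.02)
  for (alpha in c(0, 30, 60)) {
    n <- 4e5
    u <- runif(n); v <- runif(n)
    patch <- point_cloud(cbind(u * cos(alpha * pi / 180), v,
                               u * sin(alpha * pi / 180)))
    expect_equal(projected_area(patch, 0.005), cos(alpha * pi / 180),
                 tolerance = 0.03 * cos(alpha * pi / 180) + 1e-9)
  }
  # occupancy is monotone in the point set
  a <- projected_area(pc_subset(sq, 1:1000), 0.01)
  b <- projected_area(pc_subset(sq, 1:2000), 0.01)
  expect_gte(b, a)
  expect_error(projected_area(sq, 0), "positive")
})

test_that("hull volume matches analytic solids and is rigid-motion invariant", {
  expect_equal(hull_volume(tetra_cloud()), 1 / 6, tolerance = 1e-12)
  set.seed(19)
  cube <- point_cloud(matrix(runif(3e5), ncol = 3))
  v <- hull_volume(cube)
  expect_gte(v, 0.95)
  expect_lte(v, 1)
  moved <- cube
  moved$coords <- rotate_z(cube, 77)$coords + matrix(rep(c(3, -2, 10),
                                                         each = 1e5), ncol = 3)
  expect_equal(hull_volume(moved), v, tolerance = 1e-9)
  flat <- point_cloud(cbind(runif(100), runif(100), 1))
  expect_warning(v0 <- hull_volume(flat), "degenerate")
  expect_equal(v0, 0)
  expect_error(hull_volume(point_cloud(cbind(0, 0, 0))), "4 points")
})

test_that("PAI counts overlapping leaves multiply", {
  set.seed(20)
  n <- 4e5
  one <- point_cloud(cbind(runif(n), runif(n), 0), label = rep(1L, n))
  expect_lt(abs(pai(one, 0.005) - 1), 0.05)
  two <- point_cloud(rbind(one$coords, cbind(runif(n), runif(n), 0.3)),
                     label = rep(c(1L, 2L), each = n))
  expect_lt(abs(pai(two, 0.005) - 2 * pai(one, 0.005)), 0.1)
  # overlap inequality: PAI >= plant projected area / footprint
  fp <- tlsrhythm:::footprint_area(two)
  expect_gte(pai(two, 0.005) + 1e-9, projected_area(two, 0.005) / fp - 0.02)
  expect_error(pai(point_cloud(cbind(0, 0, 0), label = 1L), 0.005),
               "footprint")
})

test_that("the 3D profile index measures vertical fullness", {
  line <- point_cloud(cbind(0, 0, seq(0, 1, length.out = 200)))
  expect_equal(profile_index_3d(line, 0.02), 1)
  # all mass in the bottom layer, bounding box forced tall by one point
  slab <- point_cloud(rbind(cbind(runif(2000), runif(2000), 0.001),
                            c(0.5, 0.5, 0.999)))
  L <- ceiling((max(slab$coords[, 3]) - min(slab$coords[, 3])) / 0.02)
  v <- profile_index_3d(slab, 0.02)
  expect_lt(v, 0.05)
  expect_gte(v, 1 / L)
  set.seed(21)
  for (i in 1:5) {
    cl <- point_cloud(matrix(runif(3000, 0, 2), ncol = 3))
    v <- profile_index_3d(cl, 0.05)
    expect_gt(v, 0); expect_lte(v, 1)
  }
})

test_that("plant_traits_all assembles the nine traits coherently", {
  stem <- plant_spec(2, leaves = list())
  cl <- sample_plant(stem, 5e4, 0.002, seed = 22)
  # a bare stem has no preferred horizontal direction: azimuth is flagged
  expect_warning(tr <- plant_traits_all(cl), "unstable")
  expect_equal(tr$pla, 0)
  expect_equal(tr$pai, 0)
  expect_named(tr, c("h_max", "h_mean", "h_99", "crown_size", "azimuth_deg",
                     "pla", "volume", "pai", "profile_3d"))
  # synthetic plateau plant: H_max within 5 mm of the spec apex
  sp <- random_plant_spec(n_leaves = 8, seed = 23)
  pcl <- sample_plant(sp, 2e5, 0.002, seed = 24)
  tr2 <- plant_traits_all(pcl)
  expect_lt(abs(tr2$h_max - tlsrhythm:::plant_apex_height(sp)), 0.005)
  expect_true(tr2$h_99 <= tr2$h_max)
  # permutation invariance
  perm <- tlsrhythm:::pc_subset(pcl, sample(n_points(pcl)))
  tr3 <- plant_traits_all(perm)
  expect_equal(tr3$h_max, tr2$h_max)
  expect_equal(tr3$volume, tr2$volume, tolerance = 1e-9)
  expect_equal(tr3$pla, tr2$pla)
})

test_that("uniform scaling transforms crown, PLA and volume as expected", {
  sp <- random_plant_spec(n_leaves = 6, seed = 25)
  cl <- sample_plant(sp, 5e4, 0.002, seed = 26)
  s <- 2
  scaled <- cl
  scaled$coords <- cl$coords * s
  expect_equal(crown_size(scaled), s * crown_size(cl), tolerance = 1e-9)
  expect_equal(projected_area(scaled, 0.01), s^2 * projected_area(cl, 0.005),
               tolerance = 0.02 * s^2 * projected_area(cl, 0.005))
  expect_equal(hull_volume(scaled), s^3 * hull_volume(cl), tolerance = 1e-9)
})

test_that("plant traits grow monotonically over a logistic season", {
  base <- random_plant_spec(n_leaves = 6, seed = 27)
  stages <- as.POSIXct("2019-03-25 12:00:00", tz = "UTC") +
    stage_days()[1:3] * 86400
  sim <- simulate_series(base, growth_model(), NULL, stages,
                         as.POSIXct("2019-03-25 12:00:00", tz = "UTC"),
                         density = 3e4, seed = 28)
  tr <- do.call(rbind, lapply(sim$clouds, plant_traits_all))
  expect_true(all(diff(tr$h_max) > -0.01))
  expect_true(all(diff(tr$pla) > -0.001))
  expect_true(all(diff(tr$volume) > -0.001))
})
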