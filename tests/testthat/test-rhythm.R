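test_that("tukey_cld pairwise p-values equal the stats::TukeyHSD oracle", {
  set.seed(41)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(5:20, 1), mean = runif(1, 0, 2)))
    names(groups) <- paste0("g", seq_len(k))
    res <- tukey_cld(groups)
    df <- data.frame(v = unlist(groups),
                     f = factor(rep(names(groups),
                                    vapply(groups, length, 0L))))
    oracle <- stats::TukeyHSD(stats::aov(v ~ f, df))$f
    for (row in rownames(oracle)) {
      ab <- strsplit(row, "-")[[1]]
      expect_equal(res$p[ab[1], ab[2]], oracle[row, "p adj"],
                   tolerance = 1e-6)
    }
  }
})

test_that("compact letters encode total separation and total identity", {
  sep <- lapply(c(0, 10, 20, 30), function(m) rnorm(30, m, 0.01))
  names(sep) <- paste0("d", 1:4)
  expect_equal(length(unique(tukey_cld(sep)$letters)), 4)
  same <- replicate(4, rep(1.5, 10), simplify = FALSE)
  names(same) <- paste0("d", 1:4)
  expect_true(all(tukey_cld(same)$letters == "a"))
  expect_error(tukey_cld(list(a = 1:3)), "2 groups")
  expect_error(tukey_cld(list(a = 1, b = 1:3)), "n >= 2")
})

test_that("letter sharing matches the pairwise significance matrix", {
  set.seed(42)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(12, runif(1, 0, 1.5), 1))
    names(groups) <- paste0("g", seq_len(k))
    res <- tukey_cld(groups, alpha = 0.05)
    shares <- function(i, j) {
      any(strsplit(res$letters[i], "")[[1]] %in%
            strsplit(res$letters[j], "")[[1]])
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      expect_identical(shares(i, j), res$p[i, j] >= 0.05,
                       label = sprintf("rep %d pair %d-%d", rep, i, j))
    }
  }
})

test_that("hourly growth rate is the mean difference per hour", {
  expect_equal(hourly_rate(1.000, 78, 1.816, 112), 0.816 / 816)
  expect_equal(hourly_rate(2, 78, 2, 112), 0)
  expect_lt(hourly_rate(3, 78, 2, 112), 0)
  expect_error(hourly_rate(1, 112, 2, 78), "exceed")
})

test_that("de-trending removes exactly the linear component", {
  t0 <- as.POSIXct("2019-06-22 19:49:00", tz = "UTC")
  times <- t0 + c(0, 12, 24) * 3600
  corrected <- detrend_series(times, c(2.000, 2.012, 2.024), 0.001)
  expect_equal(corrected, rep(2, 3), tolerance = 1e-12)
  raw <- c(5, 6, 7)
  expect_identical(detrend_series(times, raw, 0), raw)
  # de-trend / re-trend round trip is the identity
  set.seed(43)
  vals <- rnorm(16)
  times16 <- t0 + sort(sample(0:26, 16)) * 3600
  round_trip <- retrend_series(times16,
                               detrend_series(times16, vals, 0.0123),
                               0.0123)
  expect_equal(round_trip, vals, tolerance = 1e-12)
})

test_that("de-trending a linear-plus-sine series recovers the sine", {
  t0 <- as.POSIXct("2019-06-22 00:00:00", tz = "UTC")
  hours <- seq(0, 26, length.out = 16)
  times <- t0 + hours * 3600
  raw <- 1 + 0.001 * hours + 0.02 * sin(2 * pi * hours / 24)
  corrected <- detrend_series(times, raw, 0.001)
  # oracle: least-squares sine fit of the corrected series
  fit <- stats::lm(corrected ~ sin(2 * pi * hours / 24) +
                     cos(2 * pi * hours / 24))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 0.02, tolerance = 0.05 * 0.02)
})

test_that("natural spline interpolation is exact where it must be", {
  t0 <- as.POSIXct("2019-06-22 00:00:00", tz = "UTC")
  knots <- t0 + seq(0, 24 * 3600, by = 1800)
  h <- as.numeric(difftime(knots, t0, units = "hours"))
  env <- structure(data.frame(time = knots, par = pmax(0, sin(pi * h / 24)),
                              temperature = 20 + 5 * h / 24,
                              rh = 50 + h / 2),
                   class = c("env_series", "data.frame"))
  at_knots <- spline_interp(env, knots[c(3, 17, 40)])
  expect_equal(at_knots$temperature, env$temperature[c(3, 17, 40)],
               tolerance = 1e-9)
  # linear data reproduced exactly between knots
  mids <- knots[-1] - 900
  expect_equal(spline_interp(env, mids)$temperature,
               20 + 5 * (h[-1] - 0.25) / 24, tolerance = 1e-9)
  expect_error(spline_interp(env, t0 - 3600), "extrapolation")
})

test_that("spline interpolation of a 24 h sine is accurate at quarter hours", {
  t0 <- as.POSIXct("2019-06-22 00:00:00", tz = "UTC")
  knots <- t0 + seq(0, 48 * 3600, by = 1800)
  h <- as.numeric(difftime(knots, t0, units = "hours"))
  env <- structure(data.frame(time = knots,
                              temperature = sin(2 * pi * h / 24)),
                   class = c("env_series", "data.frame"))
  q <- t0 + seq(6 * 3600, 42 * 3600, by = 900)
  hq <- as.numeric(difftime(q, t0, units = "hours"))
  got <- spline_interp(env, q, vars = "temperature")$temperature
  expect_lt(max(abs(got - sin(2 * pi * hq / 24))), 1e-4)
})

test_that("pearson correlation matches the closed formula and tiers", {
  x <- seq_len(16)
  strong <- pearson_env(2 * x + 1, x)
  expect_equal(strong$r, 1, tolerance = 1e-12)
  expect_identical(strong$tier, "p<0.001")
  x4 <- c(1, 2, 3, 4); y4 <- c(2, 1, 4, 3)
  res <- pearson_env(x4, y4)
  oracle <- sum((x4 - mean(x4)) * (y4 - mean(y4))) /
    sqrt(sum((x4 - mean(x4))^2) * sum((y4 - mean(y4))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  # affine invariance (positive slope)
  set.seed(44)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_env(3 * a + 2, b)$r, pearson_env(a, b)$r,
               tolerance = 1e-12)
  expect_warning(flag <- pearson_env(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(flag$r))
  expect_error(pearson_env(1:3, 1:4), "equal length")
})

test_that("p tiers follow the 0.05 / 0.01 / 0.001 thresholds", {
  expect_identical(tlsrhythm:::p_tier(0.2), "ns")
  expect_identical(tlsrhythm:::p_tier(0.04), "p<0.05")
  expect_identical(tlsrhythm:::p_tier(0.009), "p<0.01")
  expect_identical(tlsrhythm:::p_tier(0.0009), "p<0.001")
})

test_that("the circadian pipeline correlates traits with the environment", {
  moments <- circadian_moments_standard()
  env <- simulate_env(env_model(), moments[1] - 3600,
                      moments[16] + 3600, step_min = 30)
  envq <- spline_interp(env, moments)
  set.seed(45)
  trait_names <- c("h_max", "h_mean", "h_99", "crown_size", "azimuth_deg",
                   "pla", "volume", "pai", "profile_3d")
  tab <- data.frame(time = rep(moments, each = 3),
                    id = rep(1:3, times = 16))
  for (tn in trait_names) tab[[tn]] <- rnorm(nrow(tab))
  # one trait is an affine function of the interpolated temperature
  tab$pla <- rep(0.1 + 0.01 * envq$temperature, each = 3) +
    rnorm(nrow(tab), 0, 1e-6)
  out <- circadian_pipeline(tab, env)
  expect_equal(nrow(out$correlations), 9 * 3)
  expect_setequal(unique(out$correlations$factor), c("PAR", "RH", "T"))
  pla_t <- out$correlations[out$correlations$trait == "pla" &
                              out$correlations$factor == "T", ]
  expect_gte(abs(pla_t$r), 0.99)
  expect_identical(pla_t$tier, "p<0.001")
  expect_equal(nrow(out$series), 9 * 16)
})

test_that("seasonal anchors set the de-trend rate, otherwise zero", {
  moments <- circadian_moments_stress()
  env <- simulate_env(env_model(sunrise = 6.87, sunset = 17.07,
                                t_min = -2, t_max = 8),
                      moments[1] - 3600, moments[14] + 3600)
  tab <- data.frame(time = moments, h_max = seq(2, 2.15, length.out = 14))
  no_anchor <- circadian_pipeline(tab, env)
  expect_true(all(no_anchor$series$rate == 0))
  anchors <- list(day_a = 78, day_b = 112,
                  mean_a = c(h_max = 1.0), mean_b = c(h_max = 1.816))
  with_anchor <- circadian_pipeline(tab, env, anchors)
  expect_equal(unique(with_anchor$series$rate), 0.001)
  expect_equal(with_anchor$series$corrected[1],
               with_anchor$series$raw[1])
})

test_that("seasonal_analysis emits one letter row per trait and stage", {
  set.seed(46)
  tab <- data.frame(stage = rep(c("D67", "D78", "D98", "D112"), each = 8),
                    h_max = c(rnorm(8, 1), rnorm(8, 1.6), rnorm(8, 2.05),
                              rnorm(8, 2.08)) * 0.05 +
                      rep(c(1, 1.6, 2.05, 2.08), each = 8),
                    pla = rnorm(32, 0.5, 0.05))
  out <- seasonal_analysis(tab)
  expect_equal(nrow(out), 2 * 4)
  expect_true(all(c("trait", "stage", "mean", "sd", "n", "letters")
                  %in% names(out)))
})
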