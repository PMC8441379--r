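#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the workflow in one place. `mode` selects the
#' experiment: `"seasonal"` (four growth stages, Tukey letters),
#' `"circadian_standard"` (16 moments, seasonal de-trend anchors at days 78
#' and 112) or `"circadian_stress"` (14 moments, no seasonal anchors, rate
#' 0).
#'
#' @param mode experiment mode.
#' @param out_dir output directory.
#' @param seed integer RNG seed, recorded in every output.
#' @param n_plants number of simulated plants.
#' @param density sampling density, points/m^2.
#' @param noise_sd sensor noise sd, m.
#' @param spacing planting grid interval, m.
#' @param cell_size raster cell for projected areas, m.
#' @param voxel voxel size for the profile index, m.
#' @param n_slices midrib slices.
#' @param alpha Tukey significance level.
#' @param k_neighbors,n_sigma statistical outlier removal parameters.
#' @param dtm_cell DTM cell size, m.
#' @param anchor_days de-trend anchor day pair (days after planting).
#' @param planting `POSIXct` planting time.
#' @param write_clouds write per-moment clouds as XYZL files.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("seasonal", "circadian_standard",
                                "circadian_stress"),
                       out_dir = tempfile("tlsrhythm_run_"), seed = 1,
                       n_plants = 10, density = 5e4, noise_sd = 0.002,
                       spacing = 0.6, cell_size = 0.005, voxel = 0.02,
                       n_slices = 30, alpha = 0.05, k_neighbors = 20,
                       n_sigma = 3, dtm_cell = 0.25,
                       anchor_days = c(78, 112),
                       planting = as.POSIXct("2019-03-25 12:00:00",
                                             tz = "UTC"),
                       write_clouds = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_plants >= 1, density > 0, noise_sd >= 0, spacing > 0,
            cell_size > 0, voxel > 0, n_slices >= 2,
            alpha > 0, alpha < 1, k_neighbors >= 1, n_sigma > 0,
            dtm_cell > 0, length(anchor_days) == 2,
            anchor_days[2] > anchor_days[1])
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 n_plants = n_plants, density = density,
                 noise_sd = noise_sd, spacing = spacing,
                 cell_size = cell_size, voxel = voxel, n_slices = n_slices,
                 alpha = alpha, k_neighbors = k_neighbors,
                 n_sigma = n_sigma, dtm_cell = dtm_cell,
                 anchor_days = anchor_days, planting = planting,
                 write_clouds = write_clouds), class = "run_config")
}

# planting grid centers for n plants at `spacing`
grid_centers_for <- function(n, spacing) {
  side <- ceiling(sqrt(n))
  g <- expand.grid(x = (seq_len(side) - 1) * spacing,
                   y = (seq_len(side) - 1) * spacing)
  as.matrix(g[seq_len(n), , drop = FALSE])
}

log_stage <- function(stage, t0) {
  message(sprintf("[%s] %-12s (%.1f s elapsed)",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0))
}

# simulate a field cloud (plants on the grid + ground returns) per moment
simulate_field_series <- function(specs, centers, growth, circ, moments,
                                  config) {
  sim <- simulate_series(specs, growth, circ, moments, config$planting,
                         density = config$density,
                         noise_sd = config$noise_sd, seed = config$seed)
  # ground plane points so DTM normalization has returns in every cell; the
  # scanner samples soil at the same areal density as foliage
  pad <- 0.7
  xr <- range(centers[, 1]) + c(-pad, pad)
  yr <- range(centers[, 2]) + c(-pad, pad)
  gd <- config$density
  with_seed(config$seed + 1L, {
    for (m in seq_along(sim$clouds)) {
      ng <- rpois(1, gd * diff(xr) * diff(yr))
      ground <- point_cloud(cbind(runif(ng, xr[1], xr[2]),
                                  runif(ng, yr[1], yr[2]),
                                  rnorm(ng, 0, config$noise_sd)),
                            label = rep(-1L, ng))
      ground$plant <- rep(NA_integer_, ng)
      sim$clouds[[m]] <- pc_bind(list(sim$clouds[[m]], ground))
    }
  })
  sim
}

extract_all_traits <- function(cloud, centers, config, moment) {
  pt_rows <- list(); lf_rows <- list()
  for (p in seq_len(nrow(centers))) {
    idx <- which(!is.na(cloud$plant) & cloud$plant == p &
                   !is.na(cloud$label) & cloud$label >= 0L)
    if (length(idx) < 10) next
    pcl <- pc_subset(cloud, idx)
    tr <- plant_traits_all(pcl, config$cell_size, config$voxel)
    tr <- cbind(data.frame(time = moment, plant = p), tr)
    pt_rows[[length(pt_rows) + 1]] <- tr
    for (k in setdiff(unique(pcl$label), 0L)) {
      lidx <- which(pcl$label == k)
      if (length(lidx) < 4 * config$n_slices) next
      lt <- tryCatch(
        leaf_traits_all(pc_subset(pcl, lidx), config$n_slices,
                        config$cell_size, stem_xy = centers[p, ]),
        error = function(e) NULL)
      if (is.null(lt)) next
      lf_rows[[length(lf_rows) + 1]] <-
        cbind(data.frame(time = moment, plant = p, leaf = k), lt)
    }
  }
  list(plant = if (length(pt_rows)) do.call(rbind, pt_rows),
       leaf = if (length(lf_rows)) do.call(rbind, lf_rows))
}

#' Run the full workflow
#'
#' Executes simulate -> preprocess -> trait extraction -> rhythm statistics
#' and writes all result CSVs plus a JSON run manifest (configuration echo,
#' package version, seed, config hash, output checksums). Reruns with the
#' same configuration are bit-identical for the deterministic stages.
#'
#' @param config a [run_config()].
#' @return The output directory path, invisibly; results are also returned
#'   as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  centers <- grid_centers_for(config$n_plants, config$spacing)

  log_stage("simulate", t0)
  specs <- with_seed(config$seed, lapply(seq_len(config$n_plants), function(p)
    random_plant_spec(base_xy = centers[p, ], seed = NULL)))
  growth <- growth_model()
  if (config$mode == "seasonal") {
    moments <- config$planting + stage_days() * 86400 + 12 * 3600
    circ <- NULL
  } else if (config$mode == "circadian_standard") {
    moments <- circadian_moments_standard()
    circ <- circadian_model()
  } else {
    moments <- circadian_moments_stress()
    # cold-stress plants: second planting, bell-mouthed stage
    growth <- growth_model(stem = list(L = 1, r = 0.12, t_mid = 68),
                           leaf_length = list(L = 1, r = 0.14, t_mid = 65),
                           leaf_width = list(L = 1, r = 0.14, t_mid = 65))
    config$planting <- as.POSIXct("2019-08-25 12:00:00", tz = "UTC")
    circ <- circadian_model(amp_height = 0.03, amp_inclination = 4,
                            amp_azimuth = 2)
  }
  sim <- simulate_field_series(specs, centers, growth, circ, moments, config)

  log_stage("preprocess", t0)
  box <- c(min(centers[, 1]) - 0.6, max(centers[, 1]) + 0.6,
           min(centers[, 2]) - 0.6, max(centers[, 2]) + 0.6)
  clouds <- lapply(sim$clouds, function(cl) {
    cl2 <- clip_box(cl, box[1], box[2], box[3], box[4])
    cl2 <- remove_outliers(cl2, config$k_neighbors, config$n_sigma)
    cl2 <- normalize_height(cl2, config$dtm_cell)
    cluster_plants(cl2, centers, max_radius = config$spacing / 2)
  })
  if (config$write_clouds)
    for (m in seq_along(clouds))
      write_cloud(clouds[[m]],
                  file.path(config$out_dir,
                            sprintf("cloud_%02d.xyz", m)), "xyz")

  log_stage("traits", t0)
  plant_tr <- list(); leaf_tr <- list()
  for (m in seq_along(clouds)) {
    res <- extract_all_traits(clouds[[m]], centers, config, moments[m])
    if (!is.null(res$plant)) plant_tr[[length(plant_tr) + 1]] <- res$plant
    if (!is.null(res$leaf)) leaf_tr[[length(leaf_tr) + 1]] <- res$leaf
  }
  plant_tr <- do.call(rbind, plant_tr)
  leaf_tr <- if (length(leaf_tr)) do.call(rbind, leaf_tr)
  write.csv(plant_tr, file.path(config$out_dir, "traits_plant.csv"),
            row.names = FALSE)
  if (!is.null(leaf_tr))
    write.csv(leaf_tr, file.path(config$out_dir, "traits_leaf.csv"),
              row.names = FALSE)

  log_stage("rhythm", t0)
  results <- list(traits_plant = plant_tr, traits_leaf = leaf_tr,
                  truth = sim$truth)
  if (config$mode == "seasonal") {
    st <- plant_tr
    st$stage <- paste0("D", stage_days())[match(st$time, moments)]
    letters_df <- seasonal_analysis(
      st[, c("stage", "h_max", "h_mean", "h_99", "crown_size",
             "azimuth_deg", "pla", "volume", "pai", "profile_3d")],
      alpha = config$alpha)
    write.csv(letters_df, file.path(config$out_dir, "seasonal_letters.csv"),
              row.names = FALSE)
    results$seasonal <- letters_df
  } else {
    env <- simulate_env(env_model(), moments[1] - 3600,
                        moments[length(moments)] + 3600, step_min = 30)
    anchors <- NULL
    if (config$mode == "circadian_standard") {
      d <- config$anchor_days
      gl <- function(day) logistic_factor(growth_model()$stem, day)
      base_mean <- mean(vapply(specs, plant_apex_height, 0))
      anchors <- list(day_a = d[1], day_b = d[2],
                      mean_a = c(h_max = base_mean * gl(d[1])),
                      mean_b = c(h_max = base_mean * gl(d[2])))
    }
    keep <- c("time", "plant", "h_max", "h_mean", "h_99", "crown_size",
              "azimuth_deg", "pla", "volume", "pai", "profile_3d")
    circ_res <- circadian_pipeline(plant_tr[, keep], env, anchors)
    write.csv(circ_res$series,
              file.path(config$out_dir, "corrected_series.csv"),
              row.names = FALSE)
    write.csv(circ_res$correlations,
              file.path(config$out_dir, "env_correlations.csv"),
              row.names = FALSE)
    write.csv(env, file.path(config$out_dir, "env_series.csv"),
              row.names = FALSE)
    results$circadian <- circ_res
  }

  log_stage("manifest", t0)
  cfg <- config
  cfg$planting <- format(cfg$planting, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  outputs <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "tlsrhythm",
    version = as.character(packageVersion("tlsrhythm")),
    seed = config$seed, mode = config$mode,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, outputs))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}

#' Command-line entry point
#'
#' Parses `--key=value` arguments (mirroring [run_config()] keys, plus
#' `--mode`) and runs the pipeline. Exit codes: 0 ok, 2 configuration
#' error, 3 data error, 4 numerical failure. An executable wrapper lives in
#' `inst/scripts/tlsrhythm-run.R`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parse1 <- function(a) {
    if (!grepl("^--[A-Za-z_]+=", a)) stop("bad argument: ", a)
    kv <- sub("^--", "", a)
    k <- sub("=.*$", "", kv)
    v <- sub("^[^=]*=", "", kv)
    stats::setNames(list(v), k)
  }
  status <- tryCatch({
    opts <- do.call(c, lapply(args, parse1))
    defaults <- formals(run_config)
    cfg_args <- list()
    for (k in names(opts)) {
      if (!k %in% names(defaults)) stop("unknown option --", k)
      dv <- defaults[[k]]
      v <- opts[[k]]
      cfg_args[[k]] <- if (k %in% c("mode", "out_dir")) v
        else if (k == "planting") as.POSIXct(v, tz = "UTC")
        else if (k == "write_clouds") as.logical(v)
        else if (k == "anchor_days")
          as.numeric(strsplit(v, ",")[[1]])
        else as.numeric(v)
    }
    config <- do.call(run_config, cfg_args)
    run_pipeline(config)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("unknown option|bad argument|must|degenerate",
              conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}
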