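#' End-to-end pipeline configuration
#'
#' One flat configuration covering every stage, with defaults reproducing
#' the package's reference settings: 3-cell VRM window, 2.5 degree flatness
#' angle, 25% scene cloud rejection, minimum 3 observations per SST cell,
#' 10000-cell collinearity sample at |r| >= 0.7, 1 m land mask, 215-tree /
#' mtry-6 forests over 175 simulations of 70/30 splits, 75%/50% confidence
#' thresholds and a 50 m mapping depth limit. All randomness derives from
#' `seed`.
#'
#' @param synth a [synth_config()] for the synthetic inputs (its `seed` is
#'   overridden by `seed`).
#' @param terrain a [terrain_params()] list.
#' @param max_cloud,min_obs thermal-stage parameters.
#' @param n_cells,threshold,priority,min_depth stack-stage parameters.
#' @param rf an [rf_params()] list.
#' @param mc an [mc_params()] list (its `base_seed` is overridden by
#'   `seed`).
#' @param high,low,max_depth mapping-stage parameters.
#' @param seed global integer seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            terrain = terrain_params(),
                            max_cloud = 0.25, min_obs = 3L,
                            n_cells = 10000L, threshold = 0.7,
                            priority = DEFAULT_PRIORITY, min_depth = 1,
                            rf = rf_params(), mc = mc_params(),
                            high = 0.75, low = 0.50, max_depth = 50,
                            seed = 42L) {
  synth$seed <- as.integer(seed)
  mc$base_seed <- as.integer(seed)
  structure(list(synth = synth, terrain = terrain, max_cloud = max_cloud,
                 min_obs = as.integer(min_obs), n_cells = as.integer(n_cells),
                 threshold = threshold, priority = priority,
                 min_depth = min_depth, rf = rf, mc = mc, high = high,
                 low = low, max_depth = max_depth, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), function(x) {
    if (is.matrix(x)) as.list(as.data.frame(x)) else x
  }, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- raw$synth
  sc$rule_coefficients <- do.call(cbind, lapply(sc$rule_coefficients,
                                                unlist))
  synth <- do.call(synth_config, sc)
  pipeline_config(
    synth = synth, terrain = do.call(terrain_params, raw$terrain),
    max_cloud = raw$max_cloud, min_obs = raw$min_obs,
    n_cells = raw$n_cells, threshold = raw$threshold,
    priority = unlist(raw$priority), min_depth = raw$min_depth,
    rf = do.call(rf_params, raw$rf[!vapply(raw$rf, is.null, TRUE)]),
    mc = do.call(mc_params, raw$mc), high = raw$high, low = raw$low,
    max_depth = raw$max_depth, seed = raw$seed
  )
}

#' Generate and write the synthetic input file set
#'
#' Runs the synthetic generator and writes the fixture files a field
#' pipeline would start from: the fine bathymetry grid, one temperature and
#' one QA ASCII grid per thermal scene with a scene manifest CSV, the
#' ground-truth CSV (`drop_id,row,col,class`) and the configuration YAML.
#' Output directories are created as needed; identical configurations
#' produce byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a named list of the written paths.
#' @export
run_synth <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$synth
  depth <- generate_bathymetry(cfg)
  coll <- generate_thermal_collection(cfg, depth)
  paths <- list(bathymetry = file.path(out_dir, "bathymetry.asc"))
  write_ascii_grid(depth, paths$bathymetry)
  scene_rows <- vector("list", length(coll$scenes))
  for (i in seq_along(coll$scenes)) {
    tp <- file.path(out_dir, sprintf("scene_%02d_temp.asc", i))
    qp <- file.path(out_dir, sprintf("scene_%02d_qa.asc", i))
    write_ascii_grid(coll$scenes[[i]]$temperature, tp)
    write_ascii_grid(coll$scenes[[i]]$qa, qp)
    scene_rows[[i]] <- data.frame(temperature = basename(tp),
                                  qa = basename(qp),
                                  date = as.character(coll$scenes[[i]]$date))
  }
  paths$scene_manifest <- file.path(out_dir, "scenes.csv")
  utils::write.csv(do.call(rbind, scene_rows), paths$scene_manifest,
                   row.names = FALSE, quote = FALSE)
  stk <- .synth_stack(config, depth, coll)
  truth <- generate_ground_truth(cfg, stk$stack)
  paths$ground_truth <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(data.frame(drop_id = truth$drop_id, row = truth$row,
                              col = truth$col,
                              class = as.character(truth$class)),
                   paths$ground_truth, row.names = FALSE, quote = FALSE)
  paths$config <- file.path(out_dir, "config.yaml")
  write_config(config, paths$config)
  invisible(paths)
}

# terrain + thermal + stack stages shared by run_synth and run_pipeline
.synth_stack <- function(config, depth, coll) {
  terr <- terrain_predictors(depth, config$synth$coarse_cell_size,
                             config$terrain)
  masked <- coll
  masked$scenes <- lapply(coll$scenes, mask_clouds)
  masked <- reject_cloudy_scenes(masked, config$max_cloud)
  masked$scenes <- lapply(masked$scenes, to_celsius)
  sst <- reduce_collection(masked, config$min_obs)
  full <- build_stack(terr, sst, aoi_mask = coll$aoi_mask,
                      min_depth = config$min_depth)
  scr <- collinearity_screen(full, n_cells = config$n_cells,
                             threshold = config$threshold,
                             priority = config$priority,
                             seed = config$seed)
  list(stack = scr$stack, report = scr$report, full_stack = full,
       depth_coarse = terr$depth, n_scenes_kept = length(masked$scenes))
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes every stage in order — synthetic scene generation, terrain
#' predictors, SST compositing, stack assembly and collinearity screening,
#' the Monte Carlo forest ensemble, and vote-threshold mapping — and writes:
#' per-class metric and importance tables (CSV), the cover table (CSV), the
#' collinearity report (CSV + JSON), the confidence map (ASCII grid + JSON
#' legend), and a JSON run manifest with every parameter and seed. Rerunning
#' with the same configuration reproduces the outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the fitted ensemble, its summary, the
#'   confidence map, the cover table, the collinearity report and the
#'   written paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(msg) message(sprintf("[kelprf] %s", msg))
  stage("generating synthetic inputs")
  cfg <- config$synth
  depth <- generate_bathymetry(cfg)
  coll <- generate_thermal_collection(cfg, depth)
  stage("terrain + thermal predictors, stack assembly, collinearity screen")
  st <- .synth_stack(config, depth, coll)
  stage(sprintf("kept %d thermal scenes; %d predictors after screening",
                st$n_scenes_kept, length(st$stack$layers)))
  truth <- generate_ground_truth(cfg, st$stack)
  table <- extract_training_table(st$stack, truth)
  if (config$rf$mtry > length(st$stack$layers))
    stop("configuration error: mtry exceeds the predictor count",
         call. = FALSE)
  stage(sprintf("fitting %d Monte Carlo simulations", config$mc$n_sim))
  fit <- habitat_ensemble(class ~ ., table, rf = config$rf, mc = config$mc)
  s <- summarize_ensemble(fit)
  stage("classifying the stack and thresholding votes")
  map <- predict(fit, st$stack, type = "map", high = config$high,
                 low = config$low, depth_coarse = st$depth_coarse,
                 max_depth = config$max_depth)
  cover <- cover_table(map)

  paths <- list(
    class_metrics = file.path(out_dir, "class_metrics.csv"),
    importance = file.path(out_dir, "importance.csv"),
    accuracy = file.path(out_dir, "accuracy.csv"),
    cover = file.path(out_dir, "cover.csv"),
    collinearity_csv = file.path(out_dir, "collinearity_pairs.csv"),
    collinearity_json = file.path(out_dir, "collinearity.json"),
    confidence_map = file.path(out_dir, "confidence_map.asc"),
    legend = file.path(out_dir, "confidence_legend.json"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  utils::write.csv(data.frame(class = rownames(s$class_metrics),
                              round(s$class_metrics, 6)),
                   paths$class_metrics, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(variable = rownames(s$importance),
                              round(s$importance, 6)),
                   paths$importance, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(
    metric = c("train_accuracy_mean", "train_accuracy_sd",
               "validation_accuracy_mean", "validation_accuracy_sd",
               "overfit_gap"),
    value = round(c(s$train_accuracy, s$validation_accuracy,
                    s$overfit_gap), 6)),
    paths$accuracy, row.names = FALSE, quote = FALSE)
  utils::write.csv(cover, paths$cover, row.names = FALSE, quote = FALSE)
  utils::write.csv(st$report$pairs, paths$collinearity_csv,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sampled_cell_count = st$report$sampled_cell_count,
                            threshold = st$report$threshold,
                            dropped = st$report$dropped),
                       paths$collinearity_json, auto_unbox = TRUE,
                       digits = NA)
  cm <- grid_raster(st$stack$mask * NA, map$cell_size, map$origin)
  cm$values <- map$categories + 0
  write_ascii_grid(cm, paths$confidence_map)
  jsonlite::write_json(as.list(CONFIDENCE_CATEGORIES), paths$legend,
                       auto_unbox = TRUE)
  jsonlite::write_json(list(
    seed = config$seed,
    parameters = list(
      terrain = unclass(config$terrain), max_cloud = config$max_cloud,
      min_obs = config$min_obs, n_cells = config$n_cells,
      threshold = config$threshold, min_depth = config$min_depth,
      rf = unclass(config$rf), mc = unclass(config$mc),
      high = config$high, low = config$low, max_depth = config$max_depth),
    n_observations = nrow(table),
    n_predictors = length(st$stack$layers),
    sim_seeds = config$mc$base_seed + seq_len(config$mc$n_sim)),
    paths$manifest, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(ensemble = fit, summary = s, map = map, cover = cover,
                 report = st$report, stack = st$stack, paths = paths))
}
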