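#' The four benthic habitat classes
#' @export
HABITAT_CLASSES <- c("bare", "kelp", "mixed", "red")

#' Default habitat-rule coefficients
#'
#' Per-class coefficients on standardized (depth, VRM, median SST) for the
#' synthetic multinomial-logit habitat rule: bare substrate favors smooth
#' (low-VRM) terrain, kelp deeper/rugged/cooler cells, red turf
#' shallower/warmer cells, with the mixed class in between. Rows follow
#' [HABITAT_CLASSES].
#' @export
default_rule_coefficients <- function() {
  rbind(
    bare  = c(depth = 0.0,  vrm = -4.0, sst_median = 0.0),
    kelp  = c(depth = 3.5,  vrm = 1.2,  sst_median = -0.8),
    mixed = c(depth = 0.0,  vrm = 1.2,  sst_median = 1.0),
    red   = c(depth = -3.5, vrm = 1.2,  sst_median = 3.0)
  )
}

#' Configuration for the synthetic scene generator
#'
#' Bundles every knob of the seeded generator that emulates the three study
#' inputs: a fine-resolution bathymetry grid, a summer collection of thermal
#' scenes with cloud QA masks, and drop-camera ground truth labeled by a
#' known multinomial-logit rule on (depth, VRM, median SST). The same
#' configuration always produces bit-identical outputs.
#'
#' @param grid_shape fine-grid (rows, cols) in cells.
#' @param fine_cell_size fine cell size in meters (default 5).
#' @param coarse_cell_size analysis cell size in meters (default 30; must be
#'   an integer multiple of `fine_cell_size`).
#' @param n_scenes number of thermal scenes (default 16, a five-summer
#'   Landsat-style collection).
#' @param cloud_fraction_range length-2 range of per-scene AOI cloud
#'   fractions; scene targets are spread evenly across it.
#' @param n_drops number of camera drops (default 61).
#' @param cells_per_drop integer range of contiguous coarse cells observed
#'   per drop (default 2:5).
#' @param class_weights prior weights of the four classes, summing to 1;
#'   defaults to the 79/77/45/46 field proportions.
#' @param rule_coefficients 4 x 3 matrix of class coefficients on
#'   standardized (depth, VRM, median SST); see
#'   [default_rule_coefficients()].
#' @param noise_scale scale of the Gumbel utility noise in the label rule;
#'   0 makes labels a deterministic function of the predictors.
#' @param base_depth,relief,roughness,island_amplitude bathymetry shape
#'   parameters in meters: mean depth, large-scale relief amplitude,
#'   small-scale roughness amplitude, and island bump height. Setting
#'   relief, roughness and island_amplitude to zero yields a constant-depth
#'   grid.
#' @param n_islands number of island bumps (default 3).
#' @param scene_offset_sd,pixel_noise_sd thermal scene-to-scene offset and
#'   per-pixel noise standard deviations in degrees C.
#' @param seed integer seed; fully determines all outputs.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(1200L, 1200L),
                         fine_cell_size = 5,
                         coarse_cell_size = 30,
                         n_scenes = 16L,
                         cloud_fraction_range = c(0.02, 0.35),
                         n_drops = 61L,
                         cells_per_drop = c(2L, 5L),
                         class_weights = c(79, 77, 45, 46) / 247,
                         rule_coefficients = default_rule_coefficients(),
                         noise_scale = 0.15,
                         base_depth = 32,
                         relief = 25,
                         roughness = 1.5,
                         island_amplitude = 55,
                         n_islands = 3L,
                         scene_offset_sd = 1.2,
                         pixel_noise_sd = 0.25,
                         seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("`grid_shape` must be two positive integers", call. = FALSE)
  ratio <- coarse_cell_size / fine_cell_size
  if (fine_cell_size <= 0 || abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("`coarse_cell_size` must be a positive integer multiple of ",
         "`fine_cell_size`", call. = FALSE)
  if (length(cloud_fraction_range) != 2L ||
      any(cloud_fraction_range < 0 | cloud_fraction_range > 1) ||
      diff(cloud_fraction_range) < 0)
    stop("`cloud_fraction_range` must be an increasing pair in [0, 1]",
         call. = FALSE)
  if (n_scenes < 1L) stop("`n_scenes` must be >= 1", call. = FALSE)
  if (length(class_weights) != 4L || any(class_weights < 0) ||
      abs(sum(class_weights) - 1) > 1e-8)
    stop("`class_weights` must be 4 probabilities summing to 1",
         call. = FALSE)
  rule_coefficients <- as.matrix(rule_coefficients)
  if (!all(dim(rule_coefficients) == c(4L, 3L)))
    stop("`rule_coefficients` must be 4 x 3 (classes x predictors)",
         call. = FALSE)
  cells_per_drop <- as.integer(cells_per_drop)
  if (length(cells_per_drop) != 2L || cells_per_drop[1] < 1L ||
      diff(cells_per_drop) < 0)
    stop("`cells_per_drop` must be an increasing integer pair", call. = FALSE)
  structure(list(
    grid_shape = grid_shape, fine_cell_size = fine_cell_size,
    coarse_cell_size = coarse_cell_size, n_scenes = as.integer(n_scenes),
    cloud_fraction_range = cloud_fraction_range,
    n_drops = as.integer(n_drops), cells_per_drop = cells_per_drop,
    class_weights = class_weights, rule_coefficients = rule_coefficients,
    noise_scale = noise_scale, base_depth = base_depth, relief = relief,
    roughness = roughness, island_amplitude = island_amplitude,
    n_islands = as.integer(n_islands), scene_offset_sd = scene_offset_sd,
    pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)
  ), class = "synth_config")
}

std_field <- function(m) {
  s <- stats::sd(m)
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

#' Generate synthetic bathymetry
#'
#' A smooth large-scale random depth field plus a spatially varying
#' small-scale roughness component (so ruggedness is not slaved to slope)
#' minus Gaussian island shoals that rise above the 1 m land threshold.
#' Depth is meters positive-down; the default configuration spans intertidal
#' (< 1 m) through > 50 m cells.
#'
#' @param cfg a [synth_config()].
#' @return a fine-resolution depth [grid_raster].
#' @export
generate_bathymetry <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  # fixed 100 m correlation scale so terrain statistics do not depend on
  # the grid extent
  hw <- max(3L, round(100 / cfg$fine_cell_size))
  large <- std_field(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), hw))
  amp <- stats::plogis(2 * std_field(
    smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), hw)))
  fine <- std_field(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 1L,
                                 passes = 1L))
  depth <- cfg$base_depth + cfg$relief * large + cfg$roughness * amp * fine
  if (cfg$island_amplitude > 0 && cfg$n_islands > 0) {
    ri <- matrix(rep(seq_len(nr), nc), nr, nc)
    ci <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (k in seq_len(cfg$n_islands)) {
      c0 <- c(stats::runif(1, 0.2, 0.8) * nr, stats::runif(1, 0.2, 0.8) * nc)
      sigma <- stats::runif(1, 0.06, 0.12) * min(nr, nc)
      a <- cfg$island_amplitude * stats::runif(1, 0.8, 1.2)
      depth <- depth - a * exp(-((ri - c0[1])^2 + (ci - c0[2])^2) /
                                 (2 * sigma^2))
    }
  }
  grid_raster(depth, cfg$fine_cell_size, c(0, 0), "m")
}

#' Generate a synthetic thermal scene collection
#'
#' Coarse-resolution Kelvin scenes sharing one spatial temperature pattern
#' (a latitudinal gradient plus a mild shallow-water warming term), each
#' with its own scene offset and per-pixel noise, and a QA bitmask carrying
#' blob-shaped cloud (bit 0) and embedded cloud-shadow (bit 1) regions.
#' Per-scene AOI cloud fractions are spread evenly across
#' `cfg$cloud_fraction_range`.
#'
#' @param cfg a [synth_config()].
#' @param depth the fine bathymetry from [generate_bathymetry()] (used for
#'   the shallow-water warming term).
#' @return a [thermal_collection()] of `cfg$n_scenes` scenes.
#' @export
generate_thermal_collection <- function(cfg, depth) {
  stopifnot(inherits(cfg, "synth_config"), is_grid_raster(depth))
  if (cfg$n_scenes < 1L) stop("`n_scenes` must be >= 1", call. = FALSE)
  set.seed(cfg$seed + 1L)
  depth_coarse <- aggregate_to_coarse(depth, cfg$coarse_cell_size)
  dv <- depth_coarse$values
  nr <- nrow(dv); nc <- ncol(dv)
  lat <- matrix(rep(seq_len(nr), nc), nr, nc) / nr       # warmer southward
  base_c <- 16 + 1.5 * lat + 1.2 * exp(-pmax(dv, 0) / 12)
  base_c[is.na(base_c)] <- 16
  # spatially varying amplitude of the scene-to-scene swings: areas differ
  # in how strongly they track the seasonal/synoptic offsets, which makes
  # the per-cell sd and range share one spatial driver
  var_amp <- exp(0.4 * std_field(
    smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                 max(2L, round(min(nr, nc) / 10)), passes = 2L)))
  blob_hw <- max(2L, round(min(nr, nc) / 12))
  n_aoi <- nr * nc
  targets <- cfg$cloud_fraction_range[1] +
    (seq_len(cfg$n_scenes) - 0.5) / cfg$n_scenes *
    diff(cfg$cloud_fraction_range)
  targets <- sample(targets)
  dates <- as.Date("2019-07-05") + round(seq(0, 1500,
                                             length.out = cfg$n_scenes))
  scenes <- vector("list", cfg$n_scenes)
  for (i in seq_len(cfg$n_scenes)) {
    offset <- stats::rnorm(1, 0, cfg$scene_offset_sd)
    noise <- matrix(stats::rnorm(nr * nc, 0, cfg$pixel_noise_sd), nr, nc)
    temp_k <- base_c + var_amp * offset + noise + 273.15
    blob <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), blob_hw,
                         passes = 2L)
    k <- round(targets[i] * n_aoi)
    qa <- matrix(0, nr, nc)
    if (k > 0) {
      cloud_idx <- order(blob, decreasing = TRUE)[seq_len(k)]
      cloud <- matrix(FALSE, nr, nc)
      cloud[cloud_idx] <- TRUE
      shadow <- cloud & shift_zero(cloud * 1, -2L, -2L) > 0
      qa[cloud] <- QA_CLOUD
      qa[shadow] <- QA_CLOUD + QA_SHADOW
    }
    scenes[[i]] <- thermal_scene(
      grid_raster(temp_k, cfg$coarse_cell_size, depth_coarse$origin, "K"),
      grid_raster(qa, cfg$coarse_cell_size, depth_coarse$origin, "bits"),
      date = dates[i]
    )
  }
  thermal_collection(scenes,
                     grid_raster(matrix(1, nr, nc), cfg$coarse_cell_size,
                                 depth_coarse$origin))
}

#' Generate drop-camera ground truth from the habitat rule
#'
#' Places `cfg$n_drops` camera drops on eligible (masked-valid, non-land)
#' coarse cells; each drop is a 4-connected random walk of
#' `cells_per_drop` cells sharing one `drop_id`, emulating the camera frame
#' drifting across adjacent cells. Every observed cell is labeled by the
#' multinomial-logit rule: class utilities are
#' `log(class_weights) + coefficients %*% z(depth, vrm, sst_median)` plus
#' Gumbel noise scaled by `noise_scale`, and the arg-max class is recorded.
#'
#' @param cfg a [synth_config()].
#' @param predictors a `predictor_stack` from [build_stack()] containing
#'   `depth`, `vrm` and `sst_median` layers.
#' @return a data.frame of class `ground_truth` with columns `drop_id`,
#'   `row`, `col`, `class` (factor over [HABITAT_CLASSES]); realized class
#'   counts in `attr(, "class_counts")`.
#' @export
generate_ground_truth <- function(cfg, predictors) {
  stopifnot(inherits(cfg, "synth_config"),
            inherits(predictors, "predictor_stack"))
  need <- c("depth", "vrm", "sst_median")
  if (!all(need %in% names(predictors$layers)))
    stop("predictors must contain depth, vrm and sst_median layers",
         call. = FALSE)
  set.seed(cfg$seed + 2L)
  mask <- predictors$mask
  nr <- nrow(mask); nc <- ncol(mask)
  eligible <- which(mask)
  if (length(eligible) < cfg$n_drops * cfg$cells_per_drop[2])
    stop("too few eligible cells for the requested drops", call. = FALSE)
  z <- vapply(predictors$layers[need], function(v) {
    vv <- v[eligible]
    (v - mean(vv)) / stats::sd(vv)
  }, matrix(0, nr, nc))          # nr x nc x 3
  records <- vector("list", cfg$n_drops)
  for (d in seq_len(cfg$n_drops)) {
    len <- sample(seq(cfg$cells_per_drop[1], cfg$cells_per_drop[2]), 1L)
    path <- integer(0)
    for (attempt in seq_len(50L)) {
      start <- sample(eligible, 1L)
      path <- start
      while (length(path) < len) {
        cur <- path[length(path)]
        i <- (cur - 1L) %% nr + 1L
        j <- (cur - 1L) %/% nr + 1L
        nbr <- c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                 if (j > 1L) cur - nr, if (j < nc) cur + nr)
        nbr <- setdiff(nbr[mask[nbr]], path)
        if (!length(nbr)) break
        path <- c(path, if (length(nbr) == 1L) nbr else sample(nbr, 1L))
      }
      if (length(path) >= max(2L, cfg$cells_per_drop[1])) break
    }
    rows <- (path - 1L) %% nr + 1L
    cols <- (path - 1L) %/% nr + 1L
    records[[d]] <- data.frame(drop_id = d, row = rows, col = cols)
  }
  truth <- do.call(rbind, records)
  # calibrate class intercepts so the marginal class mix over eligible
  # cells matches class_weights (softmax fixed point; deterministic)
  zel <- cbind(z[, , 1][eligible], z[, , 2][eligible], z[, , 3][eligible])
  base_util <- zel %*% t(cfg$rule_coefficients)
  s_cal <- max(cfg$noise_scale, 0.05)
  w <- pmax(cfg$class_weights, 1e-12)
  b0 <- log(w)
  for (it in seq_len(60L)) {
    u <- sweep(base_util, 2L, b0, `+`) / s_cal
    u <- exp(u - apply(u, 1L, max))
    p <- colMeans(u / rowSums(u))
    if (max(abs(log(w) - log(pmax(p, 1e-12)))) < 1e-4) break
    b0 <- b0 + s_cal * (log(w) - log(pmax(p, 1e-12)))
  }
  x <- cbind(z[, , 1][cbind(truth$row, truth$col)],
             z[, , 2][cbind(truth$row, truth$col)],
             z[, , 3][cbind(truth$row, truth$col)])
  util <- x %*% t(cfg$rule_coefficients)
  util <- sweep(util, 2L, b0, `+`)
  if (cfg$noise_scale > 0) {
    gum <- -log(-log(matrix(stats::runif(length(util)), nrow(util))))
    util <- util + cfg$noise_scale * gum
  }
  truth$class <- factor(HABITAT_CLASSES[max.col(util, ties.method = "first")],
                        levels = HABITAT_CLASSES)
  attr(truth, "class_counts") <- table(truth$class)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}
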