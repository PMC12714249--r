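#' Thermal scene and scene collection containers
#'
#' A thermal scene pairs a temperature grid (Kelvin as acquired) with a
#' per-pixel quality-assurance bitmask and an acquisition date. A collection
#' is an ordered list of co-registered scenes plus a 0/1 area-of-interest
#' mask used for scene-level cloud statistics.
#'
#' QA semantics: bit 0 (value 1) flags cloud, bit 1 (value 2) cloud shadow.
#'
#' @param temperature [grid_raster] of brightness temperature in Kelvin.
#' @param qa [grid_raster] of integer QA bit flags, co-registered.
#' @param date acquisition date (`Date` or coercible string).
#' @return an object of class `thermal_scene`.
#' @export
thermal_scene <- function(temperature, qa, date = as.Date("2022-07-01")) {
  stopifnot(is_grid_raster(temperature), is_grid_raster(qa))
  stopifnot_same_geom(temperature, qa, "temperature/qa")
  structure(list(temperature = temperature, qa = qa, date = as.Date(date),
                 celsius = FALSE),
            class = "thermal_scene")
}

#' @rdname thermal_scene
#' @param scenes list of `thermal_scene` objects.
#' @param aoi_mask [grid_raster] of 0/1 area-of-interest flags co-registered
#'   with the scenes; `NULL` means the whole grid.
#' @export
thermal_collection <- function(scenes, aoi_mask = NULL) {
  stopifnot(length(scenes) >= 1L,
            all(vapply(scenes, inherits, TRUE, "thermal_scene")))
  if (is.null(aoi_mask)) {
    tmpl <- scenes[[1L]]$temperature
    aoi_mask <- grid_raster(matrix(1, nrow(tmpl$values), ncol(tmpl$values)),
                            tmpl$cell_size, tmpl$origin)
  }
  for (s in scenes) stopifnot_same_geom(s$temperature, aoi_mask, "scene/AOI")
  structure(list(scenes = scenes, aoi_mask = aoi_mask),
            class = "thermal_collection")
}

#' @export
print.thermal_collection <- function(x, ...) {
  cat(sprintf("thermal_collection: %d scene%s, %d AOI cells\n",
              length(x$scenes), if (length(x$scenes) == 1) "" else "s",
              sum(x$aoi_mask$values == 1, na.rm = TRUE)))
  invisible(x)
}

#' QA bit values used for masking
#' @export
QA_CLOUD <- 1L
#' @rdname QA_CLOUD
#' @export
QA_SHADOW <- 2L

#' Mask clouded pixels in a thermal scene
#'
#' Sets temperature to nodata wherever any of the configured QA bits (cloud
#' and cloud shadow by default) is set.
#'
#' @param scene a [thermal_scene()].
#' @param bits integer whose set bits select the QA flags to mask.
#' @return the scene with masked temperatures.
#' @export
mask_clouds <- function(scene, bits = QA_CLOUD + QA_SHADOW) {
  stopifnot(inherits(scene, "thermal_scene"))
  qa <- scene$qa$values
  hit <- !is.na(qa) & bitwAnd(as.integer(qa), as.integer(bits)) > 0L
  scene$temperature$values[hit] <- NA_real_
  scene
}

#' Drop scenes with excessive cloud cover over the AOI
#'
#' Retains scenes whose nodata (masked) fraction within the AOI is at most
#' `max_cloud`; scenes strictly above the threshold are removed, preserving
#' order. Emits a warning (not an error) when nothing survives.
#'
#' @param coll a [thermal_collection()] of already cloud-masked scenes.
#' @param max_cloud maximum tolerated AOI cloud fraction (default 0.25).
#' @return the filtered collection, with attribute `n_rejected`.
#' @export
reject_cloudy_scenes <- function(coll, max_cloud = 0.25) {
  stopifnot(inherits(coll, "thermal_collection"))
  aoi <- !is.na(coll$aoi_mask$values) & coll$aoi_mask$values == 1
  frac <- vapply(coll$scenes, function(s)
    mean(is.na(s$temperature$values[aoi])), 0)
  keep <- frac <= max_cloud
  if (!any(keep))
    warning("all scenes exceed the cloud threshold; collection is empty",
            call. = FALSE)
  out <- coll
  out$scenes <- coll$scenes[keep]
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "cloud_fraction") <- frac
  out
}

#' Convert a scene from Kelvin to degrees Celsius
#'
#' @param scene a [thermal_scene()] in Kelvin.
#' @return the scene with temperatures in degrees C and `celsius = TRUE`.
#' @export
to_celsius <- function(scene) {
  stopifnot(inherits(scene, "thermal_scene"))
  if (isTRUE(scene$celsius)) return(scene)
  scene$temperature$values <- scene$temperature$values - 273.15
  scene$temperature$units <- "degC"
  scene$celsius <- TRUE
  scene
}

#' Reduce a scene collection to per-cell SST statistics
#'
#' Per cell, over the valid (unmasked) observations across scenes: the
#' arithmetic mean, the median (midpoint rule for even counts), the sample
#' (n-1) standard deviation, and the range (max minus min). Cells observed
#' fewer than `min_obs` times are nodata in all four layers.
#'
#' @param coll a [thermal_collection()] of masked, cloud-screened scenes in
#'   degrees Celsius.
#' @param min_obs minimum valid observations per cell (default 3).
#' @return a list of class `sst_stats` with [grid_raster] elements `mean`,
#'   `median`, `sd`, `range` and `n_obs`.
#' @export
reduce_collection <- function(coll, min_obs = 3L) {
  stopifnot(inherits(coll, "thermal_collection"))
  tmpl <- coll$aoi_mask
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  n_scene <- length(coll$scenes)
  if (n_scene == 0L) {
    warning("empty scene collection; SST statistics are all nodata",
            call. = FALSE)
    blank <- grid_raster(matrix(NA_real_, nr, nc), tmpl$cell_size,
                         tmpl$origin, "degC")
    return(structure(list(mean = blank, median = blank, sd = blank,
                          range = blank, n_obs = blank),
                     class = "sst_stats"))
  }
  arr <- array(NA_real_, dim = c(nr, nc, n_scene))
  for (i in seq_len(n_scene))
    arr[, , i] <- coll$scenes[[i]]$temperature$values
  n_obs <- apply(!is.na(arr), c(1, 2), sum)
  stat <- function(f) {
    m <- apply(arr, c(1, 2), f)
    m[n_obs < min_obs] <- NA_real_
    m
  }
  mk <- function(m, units = "degC")
    grid_raster(m, tmpl$cell_size, tmpl$origin, units)
  structure(list(
    mean = mk(stat(function(v) mean(v, na.rm = TRUE))),
    median = mk(stat(function(v) stats::median(v, na.rm = TRUE))),
    sd = mk(stat(function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2L) stats::sd(v) else NA_real_
    })),
    range = mk(stat(function(v) {
      v <- v[!is.na(v)]
      if (length(v)) max(v) - min(v) else NA_real_
    })),
    n_obs = mk(n_obs, units = "count")
  ), class = "sst_stats")
}
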