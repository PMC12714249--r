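#' Continuous predictor names in screening-priority order
#'
#' Earlier names are kept when a collinear pair must lose a member: depth and
#' the terrain derivatives are never dropped by default, the median is
#' preferred over the mean, and the standard deviation over the range (the
#' discarded member of each pair is the one more strongly affected by
#' outliers). One-hot geomorphon layers are exempt from screening.
#' @export
DEFAULT_PRIORITY <- c("depth", "slope", "curvature", "northness", "eastness",
                      "vrm", "sst_median", "sst_sd", "sst_mean", "sst_range")

#' Assemble the co-registered predictor stack
#'
#' Combines the coarse terrain layers, the SST statistics and the coarse
#' depth into one named stack, and builds the analysis mask: inside the AOI,
#' at least `min_depth` meters below datum (removing land and intertidal
#' cells), and valid in every layer.
#'
#' @param terrain_layers named list of coarse [grid_raster]s from
#'   [terrain_predictors()] (must include `depth` and the `gm_*` indicators).
#' @param sst_stats an `sst_stats` list from [reduce_collection()].
#' @param aoi_mask 0/1 [grid_raster] delimiting the analysis area, or `NULL`
#'   for the full grid.
#' @param min_depth minimum depth in meters kept in the mask (default 1).
#' @return an object of class `predictor_stack`: named list of value
#'   matrices (`$layers`), a logical `$mask`, cell size and origin.
#' @export
build_stack <- function(terrain_layers, sst_stats, aoi_mask = NULL,
                        min_depth = 1) {
  stopifnot(is.list(terrain_layers), inherits(sst_stats, "sst_stats"))
  layers <- c(
    terrain_layers[c("depth", "slope", "curvature", "northness", "eastness",
                     "vrm")],
    list(sst_mean = sst_stats$mean, sst_median = sst_stats$median,
         sst_sd = sst_stats$sd, sst_range = sst_stats$range),
    terrain_layers[grep("^gm_", names(terrain_layers), value = TRUE)]
  )
  if (anyNA(names(layers)) || any(!nzchar(names(layers))))
    stop("missing required layers", call. = FALSE)
  if (anyDuplicated(names(layers)))
    stop("duplicate layer names", call. = FALSE)
  tmpl <- layers[[1L]]
  for (l in layers) stopifnot_same_geom(tmpl, l, "stack layers")
  vals <- lapply(layers, `[[`, "values")
  if (is.null(aoi_mask)) {
    aoi <- matrix(TRUE, nrow(tmpl$values), ncol(tmpl$values))
  } else {
    stopifnot_same_geom(tmpl, aoi_mask, "stack/AOI")
    aoi <- !is.na(aoi_mask$values) & aoi_mask$values == 1
  }
  depth <- vals$depth
  mask <- aoi & !is.na(depth) & depth >= min_depth
  for (v in vals) mask <- mask & !is.na(v)
  structure(list(layers = vals, mask = mask, cell_size = tmpl$cell_size,
                 origin = tmpl$origin),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers, %d x %d cells, %d in mask\n",
              length(x$layers), nrow(x$mask), ncol(x$mask), sum(x$mask)))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Pearson collinearity screen over the continuous predictors
#'
#' Draws one shared random sample of masked cells, computes Pearson r for
#' every pair of continuous layers on it, and while any retained pair
#' reaches `|r| >= threshold` drops the pair member appearing later in
#' `priority`. Indicator (one-hot) layers are exempt. Pairs involving a
#' constant layer have undefined r and are recorded as not collinear with a
#' warning.
#'
#' @param stack a [build_stack()] result.
#' @param n_cells sample size (default 10000); capped at the number of
#'   masked cells with a warning.
#' @param threshold absolute correlation triggering a drop (default 0.7).
#' @param priority keep-order for continuous layers; see [DEFAULT_PRIORITY].
#' @param seed integer seed for the cell sample.
#' @return list with the screened `stack` and a `report` (class
#'   `collinearity_report`) holding the sampled cell count, every evaluated
#'   pair with its r, and the dropped layers with reasons.
#' @export
collinearity_screen <- function(stack, n_cells = 10000L, threshold = 0.7,
                                priority = DEFAULT_PRIORITY, seed = 1L) {
  stopifnot(inherits(stack, "predictor_stack"))
  cont <- intersect(priority, names(stack$layers))
  extra <- setdiff(grep("^gm_", names(stack$layers), invert = TRUE,
                        value = TRUE), cont)
  if (length(extra))
    stop("continuous layers missing from `priority`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  idx <- which(stack$mask)
  if (length(idx) == 0L) stop("empty analysis mask", call. = FALSE)
  if (n_cells > length(idx)) {
    warning(sprintf("only %d masked cells available; using all of them",
                    length(idx)), call. = FALSE)
    n_cells <- length(idx)
  }
  set.seed(seed)
  cells <- sample(idx, n_cells)
  samp <- vapply(stack$layers[cont], function(v) v[cells], numeric(n_cells))
  pairs <- utils::combn(cont, 2L)
  r <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- samp[, pairs[1L, j]]; b <- samp[, pairs[2L, j]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning(sprintf("constant layer in sample (%s/%s); r undefined, %s",
                      pairs[1L, j], pairs[2L, j], "treated as not collinear"),
              call. = FALSE)
      r[j] <- NA_real_
    } else {
      r[j] <- stats::cor(a, b)
    }
  }
  pair_df <- data.frame(name_a = pairs[1L, ], name_b = pairs[2L, ], r = r,
                        stringsAsFactors = FALSE)
  retained <- cont
  dropped <- character(0)
  reason <- character(0)
  repeat {
    live <- pair_df[!is.na(pair_df$r) & abs(pair_df$r) >= threshold &
                      pair_df$name_a %in% retained &
                      pair_df$name_b %in% retained, , drop = FALSE]
    if (nrow(live) == 0L) break
    # lowest-priority layer appearing in any violating pair goes first
    involved <- unique(c(live$name_a, live$name_b))
    victim <- involved[which.max(match(involved, priority))]
    partner_rows <- live[live$name_a == victim | live$name_b == victim, ,
                         drop = FALSE]
    partners <- setdiff(unique(c(partner_rows$name_a, partner_rows$name_b)),
                        victim)
    dropped <- c(dropped, victim)
    reason <- c(reason,
                sprintf("|r| >= %g with %s", threshold,
                        paste(partners, collapse = ", ")))
    retained <- setdiff(retained, victim)
  }
  out <- stack
  out$layers <- stack$layers[setdiff(names(stack$layers), dropped)]
  report <- structure(list(sampled_cell_count = n_cells, pairs = pair_df,
                           dropped = data.frame(name = dropped,
                                                reason = reason,
                                                stringsAsFactors = FALSE),
                           threshold = threshold, seed = seed),
                      class = "collinearity_report")
  list(stack = out, report = report)
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("collinearity screen: %d cells sampled, threshold |r| >= %g\n",
              x$sampled_cell_count, x$threshold))
  if (nrow(x$dropped) == 0L) {
    cat("  nothing dropped\n")
  } else {
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s (%s)\n", x$dropped$name[i],
                  x$dropped$reason[i]))
  }
  invisible(x)
}
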