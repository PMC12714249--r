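#' Confidence-map category codes
#'
#' The nine output categories of the vote-threshold map: each habitat class
#' at high and low confidence, plus the no-majority class. Codes are the
#' values written into the map raster.
#' @export
CONFIDENCE_CATEGORIES <- c(
  bare_high = 1L, bare_low = 2L, kelp_high = 3L, kelp_low = 4L,
  mixed_high = 5L, mixed_low = 6L, red_high = 7L, red_low = 8L,
  no_majority = 9L
)

#' Tally per-cell ensemble votes over a predictor stack
#'
#' Every simulation's fitted forest classifies every masked cell of the
#' stack; votes are counted per cell and class. Requires the ensemble to
#' have been fit with `keep_models = TRUE` on the same predictor set as the
#' stack's layers.
#'
#' @param ensemble a [habitat_ensemble()] fit.
#' @param stack a screened `predictor_stack` whose layer names cover the
#'   ensemble's predictors.
#' @return an object of class `vote_raster`: an (rows x cols x classes)
#'   count array, `n_sim`, class levels and the grid geometry.
#' @export
classify_stack <- function(ensemble, stack) {
  stopifnot(inherits(ensemble, "habitat_ensemble"),
            inherits(stack, "predictor_stack"))
  missing_layers <- setdiff(ensemble$predictors, names(stack$layers))
  if (length(missing_layers))
    stop("stack lacks predictor layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  if (any(vapply(ensemble$results, function(r) is.null(r$model), TRUE)))
    stop("ensemble was fit with keep_models = FALSE", call. = FALSE)
  idx <- which(stack$mask)
  newdata <- as.data.frame(lapply(stack$layers[ensemble$predictors],
                                  function(v) v[idx]))
  lev <- ensemble$levels
  nr <- nrow(stack$mask); nc <- ncol(stack$mask)
  votes <- array(0, dim = c(nr, nc, length(lev)),
                 dimnames = list(NULL, NULL, lev))
  counts <- matrix(0L, length(idx), length(lev))
  for (r in ensemble$results) {
    # take each forest's winning class from its tree-vote matrix with a
    # deterministic tie-break (first level); predict()'s default class
    # output breaks ties at random, which would make maps irreproducible
    tv <- predict(r$model, newdata, type = "vote")
    ki <- max.col(tv[, lev, drop = FALSE], ties.method = "first")
    counts[cbind(seq_along(idx), ki)] <- counts[cbind(seq_along(idx), ki)] + 1L
  }
  for (k in seq_along(lev)) {
    slab <- matrix(NA_real_, nr, nc)
    slab[idx] <- counts[, k]
    votes[, , k] <- slab
  }
  structure(list(votes = votes, n_sim = length(ensemble$results),
                 levels = lev, mask = stack$mask,
                 cell_size = stack$cell_size, origin = stack$origin),
            class = "vote_raster")
}

#' Vote-threshold confidence map
#'
#' Per masked cell, the plurality class and its vote fraction f decide the
#' category: f >= `high` gives the class's high-confidence category,
#' `low` <= f < `high` its low-confidence category, and f < `low` or a tied
#' plurality the no-majority category (ties are never broken in favor of a
#' class). Cells deeper than `max_depth` are removed (nodata), as are cells
#' outside the vote mask.
#'
#' @param votes a [classify_stack()] result.
#' @param high,low vote-fraction thresholds (defaults 0.75 and 0.50; both
#'   boundaries are inclusive for their tier).
#' @param depth_coarse coarse depth [grid_raster] used for the depth mask,
#'   or `NULL` to skip it.
#' @param max_depth maximum mapped depth in meters (default 50).
#' @return an object of class `confidence_map`: an integer category matrix
#'   coded per [CONFIDENCE_CATEGORIES] (NA = nodata), the thresholds and the
#'   grid geometry.
#' @export
threshold_map <- function(votes, high = 0.75, low = 0.50,
                          depth_coarse = NULL, max_depth = 50) {
  stopifnot(inherits(votes, "vote_raster"))
  if (high <= low) stop("`high` must exceed `low`", call. = FALSE)
  nr <- dim(votes$votes)[1]; nc <- dim(votes$votes)[2]
  flat <- matrix(votes$votes, nr * nc, dim(votes$votes)[3])
  top <- apply(flat, 1L, max)
  n_top <- rowSums(flat == top)
  winner <- max.col(flat, ties.method = "first")
  f <- top / votes$n_sim
  cat_codes <- rep(NA_integer_, nr * nc)
  valid <- !is.na(top)
  no_maj <- valid & (n_top > 1L | f < low)
  hi <- valid & !no_maj & f >= high
  lo <- valid & !no_maj & !hi
  class_idx <- match(votes$levels[winner], HABITAT_CLASSES)
  cat_codes[hi] <- (class_idx[hi] - 1L) * 2L + 1L
  cat_codes[lo] <- (class_idx[lo] - 1L) * 2L + 2L
  cat_codes[no_maj] <- CONFIDENCE_CATEGORIES[["no_majority"]]
  m <- matrix(cat_codes, nr, nc)
  if (!is.null(depth_coarse)) {
    stopifnot(is_grid_raster(depth_coarse))
    d <- depth_coarse$values
    m[is.na(d) | d > max_depth] <- NA_integer_
  }
  structure(list(categories = m, high = high, low = low,
                 max_depth = max_depth, cell_size = votes$cell_size,
                 origin = votes$origin),
            class = "confidence_map")
}

#' @export
print.confidence_map <- function(x, ...) {
  n_valid <- sum(!is.na(x$categories))
  cat(sprintf("confidence_map: %d x %d cells, %d mapped, %s\n",
              nrow(x$categories), ncol(x$categories), n_valid,
              sprintf("thresholds %.0f%%/%.0f%%", 100 * x$high,
                      100 * x$low)))
  invisible(x)
}

#' Percent-cover summary of a confidence map
#'
#' Percent of mapped (non-nodata) cells in each category, rolled up per
#' habitat class into high-confidence, low-confidence and total cover, plus
#' the share of each class's predictions made at high confidence, and a
#' no-majority row.
#'
#' @param map a [threshold_map()] result.
#' @return a data.frame with one row per habitat class plus `no_majority`:
#'   `high_pct`, `low_pct`, `total_pct`, `high_share_pct`.
#' @export
cover_table <- function(map) {
  stopifnot(inherits(map, "confidence_map"))
  v <- map$categories[!is.na(map$categories)]
  n <- length(v)
  if (n == 0L) stop("confidence map has no mapped cells", call. = FALSE)
  pct <- function(code) 100 * sum(v == code) / n
  rows <- lapply(seq_along(HABITAT_CLASSES), function(k) {
    hi <- pct((k - 1L) * 2L + 1L)
    lo <- pct((k - 1L) * 2L + 2L)
    tot <- hi + lo
    data.frame(class = HABITAT_CLASSES[k], high_pct = hi, low_pct = lo,
               total_pct = tot,
               high_share_pct = if (tot > 0) 100 * hi / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    class = "no_majority", high_pct = NA_real_, low_pct = NA_real_,
    total_pct = pct(CONFIDENCE_CATEGORIES[["no_majority"]]),
    high_share_pct = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Predict habitat maps from a fitted ensemble
#'
#' `type = "votes"` returns the per-cell vote tally
#' ([classify_stack()]); `type = "map"` additionally applies the
#' vote-threshold rule ([threshold_map()]).
#'
#' @param object a [habitat_ensemble()] fit with kept models.
#' @param stack a screened `predictor_stack`.
#' @param type `"map"` (default) or `"votes"`.
#' @param high,low,max_depth passed to [threshold_map()].
#' @param depth_coarse coarse depth raster for the depth mask (optional).
#' @param ... unused.
#' @return a `vote_raster` or `confidence_map`.
#' @export
predict.habitat_ensemble <- function(object, stack, type = c("map", "votes"),
                                     high = 0.75, low = 0.50,
                                     depth_coarse = NULL, max_depth = 50,
                                     ...) {
  type <- match.arg(type)
  votes <- classify_stack(object, stack)
  if (type == "votes") return(votes)
  threshold_map(votes, high = high, low = low, depth_coarse = depth_coarse,
                max_depth = max_depth)
}
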