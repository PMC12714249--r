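#' Random forest hyperparameters
#'
#' Defaults reproduce the tuned configuration used throughout the package:
#' 215 trees, 6 candidate variables per split, terminal nodes down to a
#' single observation, and no cap on node count.
#'
#' @param ntree number of trees (default 215).
#' @param mtry candidate predictors per split (default 6).
#' @param nodesize minimum terminal-node size (default 1).
#' @param maxnodes maximum nodes per tree; `NULL` = unlimited (default).
#' @return a list of class `rf_params`.
#' @export
rf_params <- function(ntree = 215L, mtry = 6L, nodesize = 1L,
                      maxnodes = NULL) {
  if (ntree < 1L) stop("`ntree` must be >= 1", call. = FALSE)
  if (mtry < 1L) stop("`mtry` must be >= 1", call. = FALSE)
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 nodesize = as.integer(nodesize), maxnodes = maxnodes),
            class = "rf_params")
}

#' Monte Carlo simulation parameters
#'
#' @param n_sim number of simulations (default 175).
#' @param train_fraction fraction of observations in each training split
#'   (default 0.70; the remainder is the external validation set).
#' @param base_seed integer; simulation i seeds the RNG with
#'   `base_seed + i`, covering both the split and the forest.
#' @param stratified draw the split per class instead of simple random
#'   (default `FALSE`; with simple random splits, a split missing a class
#'   is redrawn with a warning).
#' @param group_by_drop keep all cells of one camera drop on the same side
#'   of the split (default `FALSE`, matching a simple per-observation
#'   split).
#' @return a list of class `mc_params`.
#' @export
mc_params <- function(n_sim = 175L, train_fraction = 0.70, base_seed = 1L,
                      stratified = FALSE, group_by_drop = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  if (n_sim < 1L) stop("`n_sim` must be >= 1", call. = FALSE)
  structure(list(n_sim = as.integer(n_sim), train_fraction = train_fraction,
                 base_seed = as.integer(base_seed),
                 stratified = isTRUE(stratified),
                 group_by_drop = isTRUE(group_by_drop)),
            class = "mc_params")
}

#' Extract the training table for ground-truth observations
#'
#' One row per observation: the predictor values of its coarse cell, its
#' class label and its drop id. Observations falling on masked or nodata
#' cells are dropped and counted.
#'
#' @param stack a screened `predictor_stack`.
#' @param truth a `ground_truth` data.frame (`drop_id`, `row`, `col`,
#'   `class`).
#' @return a data.frame with `class`, `drop_id`, `row`, `col` and one column
#'   per stack layer; dropped-row count in `attr(, "n_dropped")`.
#' @export
extract_training_table <- function(stack, truth) {
  stopifnot(inherits(stack, "predictor_stack"), is.data.frame(truth))
  nr <- nrow(stack$mask); nc <- ncol(stack$mask)
  if (any(truth$row < 1L | truth$row > nr | truth$col < 1L |
            truth$col > nc))
    stop("ground-truth cells outside the grid", call. = FALSE)
  ok <- stack$mask[cbind(truth$row, truth$col)]
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(sprintf("dropped %d observation%s on masked/nodata cells",
                    n_dropped, if (n_dropped == 1) "" else "s"))
  kept <- truth[ok, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("no ground-truth observations fall on valid cells", call. = FALSE)
  feats <- lapply(stack$layers, function(v) v[cbind(kept$row, kept$col)])
  out <- cbind(data.frame(class = factor(kept$class,
                                         levels = HABITAT_CLASSES),
                          drop_id = kept$drop_id, row = kept$row,
                          col = kept$col),
               as.data.frame(feats))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

ID_COLS <- c("drop_id", "row", "col")

one_vs_rest_metrics <- function(truth, pred, levels) {
  out <- lapply(levels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    c(precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, stats::setNames(out, levels))
}

draw_split <- function(y, drop_id, mc) {
  n <- length(y)
  if (mc$group_by_drop) {
    ids <- unique(drop_id)
    take <- sample(ids, max(1L, round(mc$train_fraction * length(ids))))
    return(which(drop_id %in% take))
  }
  if (mc$stratified) {
    idx <- unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, max(1L, round(mc$train_fraction * length(ix))))))
    return(sort(unname(idx)))
  }
  sample(n, round(mc$train_fraction * n))
}

#' Fit a Monte Carlo random-forest habitat ensemble
#'
#' The package's core estimator. For each of `mc$n_sim` simulations the RNG
#' is seeded with `base_seed + i`, the observations are split into training
#' (70%) and external validation (30%) sets, a random forest is fit on the
#' training rows, and per-simulation metrics are recorded: training accuracy
#' as the complement of the out-of-bag error (1 - OOB error), validation
#' accuracy on the hold-out, one-vs-rest precision/recall/F1 per class, and
#' unscaled permutation importance (mean decrease in accuracy, in
#' percentage points) both per class and model-wide. With simple random
#' splits a draw that loses a class entirely is redrawn (with a warning).
#'
#' Rows are canonically re-ordered (by drop id, then row, then column, then
#' remaining columns) before simulation so that results do not depend on
#' the incoming row order.
#'
#' @param formula model formula, e.g. `class ~ .`; with the default the id
#'   columns (`drop_id`, `row`, `col`) are excluded automatically.
#' @param data training table from [extract_training_table()] (or any
#'   data.frame with a factor response).
#' @param rf an [rf_params()] list.
#' @param mc an [mc_params()] list.
#' @param keep_models keep every fitted forest (needed for mapping with
#'   [classify_stack()] / `predict()`; default `TRUE`).
#' @return an object of class `habitat_ensemble`: per-simulation results,
#'   predictor names, class levels, the parameter lists and the call.
#'   Methods: [print()], [summary()] (ensemble means/sds and the metric and
#'   importance tables), [predict()] (vote and confidence rasters over a
#'   predictor stack), [plot()] (importance dotchart).
#' @seealso [summarize_ensemble()], [classify_stack()], [threshold_map()]
#' @examples
#' d <- data.frame(class = factor(rep(c("bare", "kelp"), each = 30)),
#'                 depth = c(rnorm(30, 5), rnorm(30, 20)),
#'                 vrm = runif(60, 0, 0.2))
#' fit <- habitat_ensemble(class ~ depth + vrm, d,
#'                         rf = rf_params(ntree = 25, mtry = 1),
#'                         mc = mc_params(n_sim = 5))
#' summary(fit)
#' @export
habitat_ensemble <- function(formula = class ~ ., data,
                             rf = rf_params(), mc = mc_params(),
                             keep_models = TRUE) {
  stopifnot(inherits(rf, "rf_params"), inherits(mc, "mc_params"))
  cl <- match.call()
  data <- as.data.frame(data)
  # canonical pre-shuffle: metrics must not depend on incoming row order
  ord_cols <- c(intersect(ID_COLS, names(data)),
                setdiff(names(data), ID_COLS))
  data <- data[do.call(order, data[ord_cols]), , drop = FALSE]
  rownames(data) <- NULL
  resp_name <- all.vars(formula)[1]
  rhs <- attr(stats::terms(formula, data = data[setdiff(names(data),
                                                        ID_COLS)]),
              "term.labels")
  predictors <- setdiff(rhs, c(ID_COLS, resp_name))
  y <- data[[resp_name]]
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 2L))
    stop("every class needs at least 2 observations", call. = FALSE)
  if (rf$mtry > length(predictors))
    stop(sprintf("mtry (%d) exceeds the number of predictors (%d)",
                 rf$mtry, length(predictors)), call. = FALSE)
  x <- data[predictors]
  drop_id <- if ("drop_id" %in% names(data)) data$drop_id else seq_along(y)
  lev <- levels(y)
  results <- vector("list", mc$n_sim)
  for (i in seq_len(mc$n_sim)) {
    set.seed(mc$base_seed + i)
    for (redraw in seq_len(100L)) {
      tr <- draw_split(y, drop_id, mc)
      if (nlevels(droplevels(y[tr])) == nlevels(y)) break
      warning(sprintf("simulation %d: class missing from training split; %s",
                      i, "redrawing"), call. = FALSE)
    }
    fit <- randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = y[tr],
      ntree = rf$ntree, mtry = rf$mtry, nodesize = rf$nodesize,
      maxnodes = rf$maxnodes, importance = TRUE)
    train_acc <- 1 - unname(fit$err.rate[rf$ntree, "OOB"])
    hold <- setdiff(seq_along(y), tr)
    pred <- predict(fit, x[hold, , drop = FALSE])
    val_acc <- mean(pred == y[hold])
    per_class <- one_vs_rest_metrics(y[hold], pred, lev)
    imp <- randomForest::importance(fit, scale = FALSE)
    imp <- imp[, c(lev, "MeanDecreaseAccuracy"), drop = FALSE] * 100
    colnames(imp)[ncol(imp)] <- "model"
    results[[i]] <- list(
      sim_id = i,
      train_accuracy = train_acc,
      validation_accuracy = val_acc,
      per_class = per_class,
      importance = imp,
      model = if (keep_models) fit else NULL
    )
  }
  structure(list(results = results, predictors = predictors, levels = lev,
                 rf = rf, mc = mc, n_obs = length(y), call = cl),
            class = "habitat_ensemble")
}

#' @export
print.habitat_ensemble <- function(x, ...) {
  s <- summarize_ensemble(x)
  cat("Monte Carlo random-forest habitat ensemble\n")
  cat(sprintf("  %d simulations x %d trees, mtry %d, %d observations, %s\n",
              x$mc$n_sim, x$rf$ntree, x$rf$mtry, x$n_obs,
              sprintf("%d predictors", length(x$predictors))))
  cat(sprintf("  mean training accuracy    %.3f (sd %.3f)\n",
              s$train_accuracy["mean"], s$train_accuracy["sd"]))
  cat(sprintf("  mean validation accuracy  %.3f (sd %.3f)\n",
              s$validation_accuracy["mean"], s$validation_accuracy["sd"]))
  invisible(x)
}

#' Aggregate per-simulation results into ensemble summaries
#'
#' Arithmetic means and standard deviations across simulations of the
#' training and validation accuracies; the overfit gap (mean training minus
#' mean validation accuracy); per-class precision, recall and F1 averaged
#' per simulation and then across simulations (not the F1 of the mean
#' precision and recall); and per-predictor importances averaged across
#' simulations and ordered by model-wide importance.
#'
#' @param object a [habitat_ensemble()] fit (or its raw results list).
#' @return a list of class `ensemble_summary` with elements
#'   `train_accuracy`, `validation_accuracy`, `overfit_gap`,
#'   `class_metrics` (classes x precision/recall/F1) and `importance`
#'   (predictors x classes + model, sorted).
#' @export
summarize_ensemble <- function(object) {
  results <- if (inherits(object, "habitat_ensemble")) object$results
             else object
  stopifnot(length(results) >= 1L)
  tr <- vapply(results, `[[`, 0, "train_accuracy")
  va <- vapply(results, `[[`, 0, "validation_accuracy")
  pc <- Reduce(`+`, lapply(results, `[[`, "per_class")) / length(results)
  imp <- Reduce(`+`, lapply(results, `[[`, "importance")) / length(results)
  imp <- imp[order(-imp[, "model"]), , drop = FALSE]
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  structure(list(
    n_sim = length(results),
    train_accuracy = c(mean = mean(tr), sd = sd0(tr)),
    validation_accuracy = c(mean = mean(va), sd = sd0(va)),
    overfit_gap = mean(tr) - mean(va),
    class_metrics = pc,
    importance = imp
  ), class = "ensemble_summary")
}

#' @export
summary.habitat_ensemble <- function(object, ...) summarize_ensemble(object)

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble of %d simulations\n", x$n_sim))
  cat(sprintf("  training accuracy   %.3f (sd %.3f)\n",
              x$train_accuracy["mean"], x$train_accuracy["sd"]))
  cat(sprintf("  validation accuracy %.3f (sd %.3f)\n",
              x$validation_accuracy["mean"], x$validation_accuracy["sd"]))
  cat(sprintf("  overfit gap         %+.3f\n\n", x$overfit_gap))
  cat("Per-class validation metrics (mean over simulations):\n")
  print(round(x$class_metrics, 3))
  cat("\nPermutation importance (mean decrease in accuracy, % points):\n")
  print(round(x$importance, 2))
  invisible(x)
}

#' @export
plot.habitat_ensemble <- function(x, ...) {
  s <- summarize_ensemble(x)
  imp <- rev(s$importance[, "model"])
  graphics::dotchart(imp, labels = names(imp),
                     xlab = "mean decrease in accuracy (% points)",
                     main = "Model-wide variable importance", ...)
  invisible(x)
}

#' Sweep hyperparameters over reduced Monte Carlo runs
#'
#' Evaluates every combination in `grid` (any of `ntree`, `mtry`,
#' `nodesize`, `maxnodes`, `n_sim`) with a Monte Carlo run and reports the
#' mean and sd of validation accuracy per grid point, for plateau
#' inspection.
#'
#' @inheritParams habitat_ensemble
#' @param grid named list of parameter vectors to cross.
#' @return a data.frame: one row per grid point with the parameter values,
#'   `mean_validation_accuracy` and `sd_validation_accuracy`.
#' @export
tune_hyperparameters <- function(formula = class ~ ., data, grid,
                                 rf = rf_params(), mc = mc_params()) {
  allowed <- c("ntree", "mtry", "nodesize", "maxnodes", "n_sim")
  if (!length(grid) || is.null(names(grid)) ||
      !all(names(grid) %in% allowed))
    stop("`grid` must be a named list over ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (any(vapply(grid, function(v) any(v < 1), TRUE)))
    stop("grid values must be >= 1", call. = FALSE)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(pts)), function(k) {
    rf_k <- rf; mc_k <- mc
    for (nm in names(pts)) {
      if (nm == "n_sim") mc_k$n_sim <- as.integer(pts[k, nm])
      else rf_k[[nm]] <- as.integer(pts[k, nm])
    }
    fit <- habitat_ensemble(formula, data, rf = rf_k, mc = mc_k,
                            keep_models = FALSE)
    s <- summarize_ensemble(fit)
    c(mean_validation_accuracy = unname(s$validation_accuracy["mean"]),
      sd_validation_accuracy = unname(s$validation_accuracy["sd"]))
  })
  cbind(pts, do.call(rbind, res))
}
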