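test_that("extract_training_table joins observations to cells and logs drops", {
  mats <- list(depth = matrix(10, 6, 6), vrm = matrix(0.1, 6, 6),
               sst_median = matrix(17, 6, 6))
  mats$depth[1, 1] <- 0.2                      # land-masked cell
  st <- stack_from_mats(mats)
  truth <- data.frame(drop_id = c(1, 1, 2, 3), row = c(2, 2, 1, 5),
                      col = c(2, 3, 1, 5),
                      class = c("kelp", "kelp", "bare", "red"))
  expect_message(tab <- extract_training_table(st, truth), "dropped 1")
  expect_equal(nrow(tab), 3)                   # the land row is gone
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_setequal(names(tab),
                  c("class", "drop_id", "row", "col", names(mats)))
  expect_equal(tab$depth, rep(10, 3))

  # fully valid observations keep their count
  truth_ok <- truth[-3, ]
  tab2 <- extract_training_table(st, truth_ok)
  expect_equal(nrow(tab2), nrow(truth_ok))

  expect_error(extract_training_table(st, data.frame(
    drop_id = 1, row = 99, col = 1, class = "bare")), "outside")
})

test_that("a separable depth rule is learned almost perfectly", {
  tab <- separable_table(n_per = 40, seed = 1)
  fit <- habitat_ensemble(class ~ depth + vrm + sst_median, tab,
                          rf = rf_params(ntree = 100, mtry = 2),
                          mc = mc_params(n_sim = 10, base_seed = 1))
  s <- summarize_ensemble(fit)
  expect_gte(s$validation_accuracy[["mean"]], 0.95)
  expect_equal(rownames(s$importance)[1], "depth")
  expect_true(all(s$class_metrics[, "f1"] > 0.9))
})

test_that("permuted labels collapse accuracy to the majority baseline", {
  tab <- separable_table(n_per = 30, seed = 2)
  set.seed(99)
  tab$class <- sample(tab$class)
  fit <- habitat_ensemble(class ~ depth + vrm + sst_median, tab,
                          rf = rf_params(ntree = 100, mtry = 2),
                          mc = mc_params(n_sim = 15, base_seed = 3))
  s <- summarize_ensemble(fit)
  base <- max(table(tab$class)) / nrow(tab)
  expect_lt(abs(s$validation_accuracy[["mean"]] - base),
            3 * max(s$validation_accuracy[["sd"]], 0.02))
})

test_that("results are deterministic in base_seed and row-order invariant", {
  tab <- separable_table(n_per = 25, seed = 3)
  fit1 <- habitat_ensemble(class ~ depth + vrm + sst_median, tab,
                           rf = rf_params(ntree = 50, mtry = 2),
                           mc = mc_params(n_sim = 6, base_seed = 11))
  fit2 <- habitat_ensemble(class ~ depth + vrm + sst_median, tab,
                           rf = rf_params(ntree = 50, mtry = 2),
                           mc = mc_params(n_sim = 6, base_seed = 11))
  va <- function(f) vapply(f$results, `[[`, 0, "validation_accuracy")
  expect_identical(va(fit1), va(fit2))
  expect_identical(summarize_ensemble(fit1)$importance,
                   summarize_ensemble(fit2)$importance)

  shuffled <- tab[sample(nrow(tab)), ]
  fit3 <- habitat_ensemble(class ~ depth + vrm + sst_median, shuffled,
                           rf = rf_params(ntree = 50, mtry = 2),
                           mc = mc_params(n_sim = 6, base_seed = 11))
  expect_identical(va(fit1), va(fit3))

  # different seed, different split realizations (visible on noisy labels)
  noisy <- tab
  set.seed(8)
  flip <- sample(nrow(noisy), 30)
  noisy$class[flip] <- sample(noisy$class[flip])
  fit_a <- habitat_ensemble(class ~ depth + vrm + sst_median, noisy,
                            rf = rf_params(ntree = 50, mtry = 2),
                            mc = mc_params(n_sim = 6, base_seed = 11))
  fit_b <- habitat_ensemble(class ~ depth + vrm + sst_median, noisy,
                            rf = rf_params(ntree = 50, mtry = 2),
                            mc = mc_params(n_sim = 6, base_seed = 500))
  expect_false(identical(va(fit_a), va(fit_b)))
})

test_that("parameter guards fire before any training", {
  tab <- separable_table(n_per = 10)
  expect_error(habitat_ensemble(class ~ depth + vrm, tab,
                                rf = rf_params(mtry = 5),
                                mc = mc_params(n_sim = 2)),
               "mtry")
  one <- tab[tab$class == "bare", ]
  expect_error(habitat_ensemble(class ~ depth + vrm, one,
                                mc = mc_params(n_sim = 2)),
               "2 classes")
  expect_error(mc_params(train_fraction = 1), "train_fraction")
  expect_error(rf_params(ntree = 0), "ntree")
})

test_that("ensemble summaries use the documented averaging conventions", {
  mk_res <- function(va, f1, p, r) {
    pc <- matrix(c(p, r, f1), 1, 3,
                 dimnames = list("kelp", c("precision", "recall", "f1")))
    list(sim_id = 1, train_accuracy = va, validation_accuracy = va,
         per_class = pc,
         importance = matrix(va, 1, 2,
                             dimnames = list("depth", c("kelp", "model"))),
         model = NULL)
  }
  # two sims 0.6/0.8 -> mean 0.7
  s <- summarize_ensemble(list(mk_res(0.6, 1, 0.5, 1), mk_res(0.8, 0, 1, 0.5)))
  expect_equal(s$validation_accuracy[["mean"]], 0.7)
  # per-sim F1s {1, 0} with P/R means (0.75, 0.75): mean F1 is 0.5, not the
  # F1 of the mean precision and recall (~0.75)
  expect_equal(s$class_metrics["kelp", "f1"], 0.5)
  expect_equal(s$class_metrics["kelp", "precision"], 0.75)

  # identical results: sd 0, means equal to the common value
  s2 <- summarize_ensemble(list(mk_res(0.8, 1, 1, 1), mk_res(0.8, 1, 1, 1)))
  expect_equal(s2$validation_accuracy[["sd"]], 0)
  expect_equal(s2$overfit_gap, 0)
})

test_that("F1 is defined as 0 when precision and recall are both 0", {
  m <- kelprf:::one_vs_rest_metrics(
    truth = factor(c("bare", "bare", "kelp"),
                   levels = c("bare", "kelp", "mixed")),
    pred = factor(c("kelp", "kelp", "bare"),
                  levels = c("bare", "kelp", "mixed")),
    levels = c("bare", "kelp", "mixed"))
  expect_equal(unname(m["bare", "f1"]), 0)
  expect_equal(unname(m["mixed", "f1"]), 0)    # never predicted, never true
  # hand-checked harmonic mean
  t2 <- factor(c("bare", "bare", "kelp", "kelp"))
  p2 <- factor(c("bare", "kelp", "kelp", "kelp"))
  m2 <- kelprf:::one_vs_rest_metrics(t2, p2, c("bare", "kelp"))
  expect_equal(unname(m2["kelp", "precision"]), 2 / 3)
  expect_equal(unname(m2["kelp", "recall"]), 1)
  expect_equal(unname(m2["kelp", "f1"]), 2 * (2 / 3) / (2 / 3 + 1))
})

test_that("hyperparameter sweeps cover the grid and match single runs", {
  tab <- separable_table(n_per = 20, seed = 5)
  mc <- mc_params(n_sim = 4, base_seed = 2)
  tune <- tune_hyperparameters(class ~ depth + vrm + sst_median, tab,
                               grid = list(mtry = 1:3),
                               rf = rf_params(ntree = 40), mc = mc)
  expect_equal(nrow(tune), 3)
  expect_equal(tune$mtry, 1:3)
  expect_true(all(c("mean_validation_accuracy", "sd_validation_accuracy")
                  %in% names(tune)))

  # a single-point grid equals the plain Monte Carlo summary
  single <- tune_hyperparameters(class ~ depth + vrm + sst_median, tab,
                                 grid = list(ntree = 40),
                                 rf = rf_params(ntree = 40, mtry = 2), mc = mc)
  fit <- habitat_ensemble(class ~ depth + vrm + sst_median, tab,
                          rf = rf_params(ntree = 40, mtry = 2), mc = mc)
  s <- summarize_ensemble(fit)
  expect_equal(single$mean_validation_accuracy,
               s$validation_accuracy[["mean"]])

  # more trees never hurt beyond noise
  curve <- tune_hyperparameters(class ~ depth + vrm + sst_median, tab,
                                grid = list(ntree = c(50, 350)),
                                rf = rf_params(mtry = 2), mc = mc)
  expect_gte(curve$mean_validation_accuracy[2],
             curve$mean_validation_accuracy[1] -
               2 * curve$sd_validation_accuracy[1])

  expect_error(tune_hyperparameters(class ~ ., tab, grid = list(foo = 1)),
               "named list")
  expect_error(tune_hyperparameters(class ~ ., tab,
                                    grid = list(ntree = 0)), ">= 1")
})

test_that("print and plot methods run quietly", {
  tab <- separable_table(n_per = 15, seed = 6)
  fit <- habitat_ensemble(class ~ depth + vrm + sst_median, tab,
                          rf = rf_params(ntree = 30, mtry = 2),
                          mc = mc_params(n_sim = 3))
  expect_output(print(fit), "Monte Carlo")
  expect_output(print(summary(fit)), "Permutation importance")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
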