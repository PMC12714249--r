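# Small in-code fixtures shared across test files.

# tilted-plane depth grid: depth = gx * x + gy * y + c0 (x east, y north)
plane_depth <- function(nr = 8, nc = 8, gx = 0, gy = 0, c0 = 20, cs = 1) {
  x <- matrix(rep((seq_len(nc) - 0.5) * cs, each = nr), nr, nc)
  y <- matrix(rep(((nr:1) - 0.5) * cs, nc), nr, nc)
  grid_raster(gx * x + gy * y + c0, cs)
}

random_depth <- function(nr = 8, nc = 8, cs = 2, seed = 1, sd = 3) {
  set.seed(seed)
  grid_raster(matrix(20 + rnorm(nr * nc, 0, sd), nr, nc), cs)
}

# minimal predictor stack built directly from matrices
stack_from_mats <- function(mats, cell_size = 30, min_depth = 1,
                            mask = NULL) {
  tmpl <- mats[[1]]
  layers <- lapply(mats, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(mask)) {
    mask <- !is.na(layers$depth) & layers$depth >= min_depth
    for (m in layers) mask <- mask & !is.na(m)
  }
  structure(list(layers = layers, mask = mask, cell_size = cell_size,
                 origin = c(0, 0)),
            class = "predictor_stack")
}

# a vote_raster built directly from a list of per-class count matrices
votes_from_counts <- function(counts, n_sim) {
  nr <- nrow(counts[[1]]); nc <- ncol(counts[[1]])
  v <- array(NA_real_, c(nr, nc, length(counts)),
             dimnames = list(NULL, NULL, names(counts)))
  for (k in seq_along(counts)) v[, , k] <- counts[[k]]
  mask <- !is.na(counts[[1]])
  structure(list(votes = v, n_sim = n_sim, levels = names(counts),
                 mask = mask, cell_size = 30, origin = c(0, 0)),
            class = "vote_raster")
}

# a small clearly separable training table (depth threshold rule)
separable_table <- function(n_per = 40, seed = 1) {
  set.seed(seed)
  n <- 4 * n_per
  depth <- c(runif(n_per, 2, 8), runif(n_per, 12, 18),
             runif(n_per, 22, 28), runif(n_per, 32, 38))
  data.frame(
    class = factor(rep(HABITAT_CLASSES, each = n_per),
                   levels = HABITAT_CLASSES),
    drop_id = rep(seq_len(n / 2), each = 2),
    row = sample(n), col = sample(n),
    depth = depth,
    vrm = runif(n, 0, 0.3),
    sst_median = rnorm(n, 17, 0.5)
  )
}

# small synthetic scene shared by heavier tests (60 x 60 coarse cells)
small_scene <- function(seed = 7, n_sim = 6, ...) {
  cfg <- synth_config(grid_shape = c(360, 360), seed = seed, ...)
  pcfg <- pipeline_config(synth = cfg, mc = mc_params(n_sim = n_sim),
                          seed = seed)
  depth <- generate_bathymetry(cfg)
  coll <- generate_thermal_collection(cfg, depth)
  st <- suppressWarnings(kelprf:::.synth_stack(pcfg, depth, coll))
  list(cfg = cfg, pcfg = pcfg, depth = depth, coll = coll,
       stack = st$stack, full_stack = st$full_stack, report = st$report,
       depth_coarse = st$depth_coarse)
}
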