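test_that("slope and aspect are exact on planes and flats", {
  flat <- plane_depth(8, 8)
  sa <- compute_slope_aspect(flat)
  inner <- sa$slope$values[2:7, 2:7]
  expect_true(all(inner == 0))
  expect_true(all(sa$aspect$values[2:7, 2:7] == FLAT_ASPECT))
  expect_true(all(is.na(sa$slope$values[1, ])))  # border is nodata

  # 1 m/m eastward deepening: 45 degree slope, downslope due east
  east <- plane_depth(8, 8, gx = 1)
  sa <- compute_slope_aspect(east)
  expect_equal(sa$slope$values[4, 4], 45)
  expect_equal(sa$aspect$values[4, 4], 90)

  # northward deepening: downslope due north (aspect 0)
  north <- plane_depth(8, 8, gy = 1)
  sa <- compute_slope_aspect(north)
  expect_equal(sa$aspect$values[4, 4], 0)

  expect_error(compute_slope_aspect(grid_raster(matrix(NA_real_, 4, 4), 1)),
               "no valid cells")
})

test_that("slope/aspect match the per-cell Horn oracle on random grids", {
  for (seed in 1:5) {
    d <- random_depth(8, 8, cs = 2, seed = seed)
    sa <- compute_slope_aspect(d)
    o <- oracle_slope_aspect(d$values, 2)
    expect_equal(sa$slope$values, o$slope, tolerance = 1e-12)
    expect_equal(sa$aspect$values, o$aspect, tolerance = 1e-12)
  }
})

test_that("aspect components satisfy the unit-circle identities", {
  a <- grid_raster(matrix(c(0, 90, 225, FLAT_ASPECT, 137.3, 310), 2, 3), 1)
  ne <- aspect_to_components(a)
  expect_equal(ne$northness$values[1, 1], 1)
  expect_equal(ne$eastness$values[1, 1], 0)
  expect_equal(ne$northness$values[2, 1], 0)
  expect_equal(ne$eastness$values[2, 1], 1)
  expect_equal(ne$northness$values[1, 2], -sqrt(2) / 2)
  expect_equal(ne$eastness$values[1, 2], -sqrt(2) / 2)
  # flat sentinel -> (0, 0), not trigonometry on -1 degrees
  expect_equal(ne$northness$values[2, 2], 0)
  expect_equal(ne$eastness$values[2, 2], 0)
  # norm 1 where aspect is defined, 0 on flat cells
  nn <- ne$northness$values^2 + ne$eastness$values^2
  expect_equal(nn[, c(1, 3)], matrix(1, 2, 2))
  expect_equal(nn[2, 2], 0)
})

test_that("mean curvature is zero on planes and exact on a paraboloid", {
  tilted <- plane_depth(8, 8, gx = 0.7, gy = -0.3)
  cv <- compute_mean_curvature(tilted)
  expect_equal(cv$values[2:7, 2:7], matrix(0, 6, 6), tolerance = 1e-10)

  # depth = x^2 + y^2 (shoal mound in elevation): z_xx = z_yy = -2,
  # curvature = -100 * (-2) = +200 at every interior cell
  nr <- 9
  x <- matrix(rep(seq_len(nr) - 5, each = nr), nr, nr)
  y <- t(x)
  par <- grid_raster(x^2 + y^2 + 50, 1)
  cv <- compute_mean_curvature(par)
  expect_equal(cv$values[3:7, 3:7], matrix(200, 5, 5), tolerance = 1e-9)
})

test_that("curvature matches the exact quadric-solve oracle on random grids", {
  for (seed in 1:5) {
    d <- random_depth(8, 8, cs = 2, seed = seed)
    cv <- compute_mean_curvature(d)
    expect_equal(cv$values, oracle_mean_curvature(d$values, 2),
                 tolerance = 1e-9)
  }
})

test_that("VRM is zero on planes and matches the hand-evaluated window", {
  # uniform inclined plane: identical normals everywhere
  sa <- compute_slope_aspect(plane_depth(10, 10, gx = 0.5))
  vrm <- compute_vrm(sa$slope, sa$aspect)
  inner <- vrm$values[3:8, 3:8]
  expect_equal(inner, matrix(0, 6, 6), tolerance = 1e-12)

  # 4 cells facing north + 4 facing south at 45 deg + 1 flat cell:
  # resultant = (0, 0, 8 cos45 + 1), VRM = 1 - 6.6569/9
  s <- matrix(45, 3, 3); s[2, 2] <- 0
  a <- matrix(c(0, 180, 0, 180, -1, 0, 180, 0, 180), 3, 3)
  vrm <- compute_vrm(grid_raster(s, 1), grid_raster(a, 1))
  expect_equal(vrm$values[2, 2], 1 - (8 * cos(pi / 4) + 1) / 9,
               tolerance = 1e-12)
  expect_equal(round(vrm$values[2, 2], 4), 0.2603)
})

test_that("VRM stays in [0,1] and matches the per-cell oracle", {
  for (seed in 1:5) {
    d <- random_depth(12, 10, cs = 2, seed = seed)
    sa <- compute_slope_aspect(d)
    vrm <- compute_vrm(sa$slope, sa$aspect)
    v <- vrm$values[!is.na(vrm$values)]
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(vrm$values, oracle_vrm(sa$slope$values, sa$aspect$values, 3),
                 tolerance = 1e-12)
  }
  sa <- compute_slope_aspect(random_depth(4, 4))
  expect_error(compute_vrm(sa$slope, sa$aspect,
                           terrain_params(vrm_window = 5)),
               "exceeds the grid")
})

test_that("VRM grows as window normals disperse from a common direction", {
  base <- matrix(30, 3, 3)
  asp <- matrix(0, 3, 3)
  vrm0 <- compute_vrm(grid_raster(base, 1), grid_raster(asp, 1))$values[2, 2]
  prev <- vrm0
  for (spread in c(10, 25, 45)) {
    a2 <- matrix(c(0, spread, -spread, spread, 0, -spread,
                   spread, -spread, 0), 3, 3)
    v <- compute_vrm(grid_raster(base, 1), grid_raster(a2, 1))$values[2, 2]
    expect_gt(v, prev)
    prev <- v
  }
})

test_that("geomorphons classify canonical landforms", {
  p <- terrain_params(geomorphon_lookup = 3)
  # constant depth: flat everywhere
  gm <- compute_geomorphons(plane_depth(9, 9), p)
  expect_true(all(gm$values == GEOMORPHON_FORMS[["flat"]]))

  # steep conical shoal: apex sees every direction downward -> ridge
  nr <- 11
  x <- matrix(rep(seq_len(nr) - 6, each = nr), nr, nr)
  y <- t(x)
  cone <- grid_raster(5 + 3 * sqrt(x^2 + y^2), 1)
  gm <- compute_geomorphons(cone, p)
  expect_equal(gm$values[6, 6], unname(GEOMORPHON_FORMS[["ridge"]]))

  # axis-aligned V trench (deepest along column 6): floor cells -> valley
  v <- grid_raster(matrix(rep(20 - 3 * abs(seq_len(11) - 6), each = 11),
                          11, 11), 1)
  gm <- compute_geomorphons(v, p)
  expect_equal(gm$values[4:8, 6], rep(unname(GEOMORPHON_FORMS[["valley"]]), 5))

  expect_error(terrain_params(geomorphon_lookup = 0), "must be >= 1")
})

test_that("geomorphons match the line-of-sight oracle on random grids", {
  p <- terrain_params(geomorphon_lookup = 4)
  for (seed in 1:5) {
    d <- random_depth(16, 16, cs = 2, seed = seed, sd = 1.5)
    gm <- compute_geomorphons(d, p)
    expect_equal(gm$values, oracle_geomorphons(d$values, 2, 4, 2.5))
  }
})

test_that("one-hot geomorphon layers partition the valid cells", {
  d <- random_depth(16, 16, cs = 2, seed = 3, sd = 1.5)
  gm <- compute_geomorphons(d, terrain_params(geomorphon_lookup = 4))
  oh <- one_hot_geomorphons(gm)
  expect_length(oh, 6)
  expect_named(oh, names(GEOMORPHON_FORMS))
  tot <- Reduce(`+`, lapply(oh, `[[`, "values"))
  expect_true(all(tot[!is.na(tot)] == 1))
  for (l in oh) expect_true(all(l$values[!is.na(l$values)] %in% c(0, 1)))

  # all-flat input: flat layer 1, others 0
  gm_flat <- compute_geomorphons(plane_depth(6, 6),
                                 terrain_params(geomorphon_lookup = 2))
  oh <- one_hot_geomorphons(gm_flat)
  expect_true(all(oh$flat$values == 1))
  for (nm in setdiff(names(oh), "flat"))
    expect_true(all(oh[[nm]]$values == 0))

  bad <- gm
  bad$values[2, 2] <- 99
  expect_error(one_hot_geomorphons(bad), "unknown geomorphon")
})

test_that("aggregation averages continuous and votes one-hot layers", {
  m <- grid_raster(matrix(1:36, 6, 6), 5)
  agg <- aggregate_to_coarse(m, 30)
  expect_equal(dim(agg$values), c(1L, 1L))
  expect_equal(agg$values[1, 1], 18.5)
  expect_equal(agg$cell_size, 30)

  oh <- matrix(0, 6, 6); oh[1:20] <- 1     # 20/36 ones -> majority 1
  expect_equal(aggregate_to_coarse(grid_raster(oh, 5), 30,
                                   method = "majority")$values[1, 1], 1)
  oh[4:20] <- 0                            # 3/36 -> majority 0
  expect_equal(aggregate_to_coarse(grid_raster(oh, 5), 30,
                                   method = "majority")$values[1, 1], 0)

  const <- aggregate_to_coarse(grid_raster(matrix(7, 12, 18), 5), 30)
  expect_true(all(const$values == 7))

  # empty coarse cells are nodata; valid ones ignore NA fine cells
  h <- matrix(NA_real_, 6, 12); h[, 7:12] <- 2
  agg <- aggregate_to_coarse(grid_raster(h, 5), 30)
  expect_true(is.na(agg$values[1, 1]))
  expect_equal(agg$values[1, 2], 2)

  expect_error(aggregate_to_coarse(m, 2), "must exceed")
})

test_that("aggregation supports non-integer resolution ratios", {
  # 4 m -> 30 m: 7.5 fine cells per coarse cell
  set.seed(9)
  fine <- grid_raster(matrix(rnorm(60 * 60), 60, 60), 4)
  agg <- aggregate_to_coarse(fine, 30)
  expect_equal(dim(agg$values), c(8L, 8L))
  # spot-check one coarse cell against direct center membership
  cx <- (seq_len(60) - 0.5) * 4
  in_cell <- function(ci, cj)
    mean(fine$values[cx >= (ci - 1) * 30 & cx < ci * 30,
                     cx >= (cj - 1) * 30 & cx < cj * 30])
  expect_equal(agg$values[2, 3], in_cell(2, 3))
  expect_equal(agg$values[1, 1], in_cell(1, 1))
})

test_that("integer-ratio aggregation preserves the global mean", {
  for (seed in 1:3) {
    set.seed(seed)
    fine <- grid_raster(matrix(rnorm(36 * 24), 36, 24), 5)
    agg <- aggregate_to_coarse(fine, 30)
    expect_equal(mean(agg$values), mean(fine$values), tolerance = 1e-12)
  }
})
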