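#' Terrain analysis parameters
#'
#' @param vrm_window odd window width in cells for the vector ruggedness
#'   measure (default 3, i.e. a 3x3 neighborhood).
#' @param flatness_angle line-of-sight relief angle in degrees below which a
#'   direction is coded level in geomorphon classification (default 2.5).
#' @param geomorphon_lookup search radius in cells for geomorphon
#'   line-of-sight angles (default 10).
#' @param curvature_scale multiplier applied to mean curvature; the default
#'   100 reports curvature per 100 m, the common GIS convention.
#' @return a list of class `terrain_params`.
#' @export
terrain_params <- function(vrm_window = 3L, flatness_angle = 2.5,
                           geomorphon_lookup = 10L, curvature_scale = 100) {
  vrm_window <- as.integer(vrm_window)
  if (vrm_window < 3L || vrm_window %% 2L == 0L)
    stop("`vrm_window` must be an odd integer >= 3", call. = FALSE)
  if (flatness_angle <= 0)
    stop("`flatness_angle` must be positive", call. = FALSE)
  geomorphon_lookup <- as.integer(geomorphon_lookup)
  if (geomorphon_lookup < 1L)
    stop("`geomorphon_lookup` must be >= 1", call. = FALSE)
  structure(list(vrm_window = vrm_window, flatness_angle = flatness_angle,
                 geomorphon_lookup = geomorphon_lookup,
                 curvature_scale = curvature_scale),
            class = "terrain_params")
}

#' Aspect sentinel for flat cells
#'
#' Cells with zero gradient have no defined downslope direction; slope/aspect
#' functions mark them with this sentinel instead of an angle, and
#' [aspect_to_components()] maps them to northness = eastness = 0.
#' @export
FLAT_ASPECT <- -1

# Horn 3x3 gradient of the *surface elevation* (z = -depth), returning
# per-cell dz/dx (eastward) and dz/dy (northward). Border cells and cells
# with any missing neighbor are NA.
horn_gradient <- function(depth) {
  z <- -depth$values
  cs <- depth$cell_size
  nb <- list(
    a = shift_matrix(z, -1L, -1L), b = shift_matrix(z, -1L, 0L),
    c = shift_matrix(z, -1L, 1L),  d = shift_matrix(z, 0L, -1L),
    f = shift_matrix(z, 0L, 1L),   g = shift_matrix(z, 1L, -1L),
    h = shift_matrix(z, 1L, 0L),   i = shift_matrix(z, 1L, 1L)
  )
  dzdx <- ((nb$c + 2 * nb$f + nb$i) - (nb$a + 2 * nb$d + nb$g)) / (8 * cs)
  # row index grows southward, so the northward derivative flips sign
  dzdy <- ((nb$a + 2 * nb$b + nb$c) - (nb$g + 2 * nb$h + nb$i)) / (8 * cs)
  bad <- is.na(z)
  dzdx[bad] <- NA; dzdy[bad] <- NA
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Slope and aspect of a depth raster
#'
#' Horn's 3x3 finite-difference method applied to the seafloor surface
#' (elevation = negative depth). Slope is degrees from horizontal; aspect is
#' the downslope compass direction in degrees clockwise from grid north,
#' in \[0, 360). Zero-gradient cells receive slope 0 and the [FLAT_ASPECT]
#' sentinel; cells on the border or adjacent to nodata are nodata.
#'
#' @param depth a [grid_raster] of depth in meters, positive down.
#' @return a list with [grid_raster] elements `slope` and `aspect`.
#' @export
compute_slope_aspect <- function(depth) {
  stopifnot(is_grid_raster(depth))
  if (all(is.na(depth$values)))
    stop("depth raster has no valid cells", call. = FALSE)
  g <- horn_gradient(depth)
  slope <- atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi
  # downslope direction = -(gradient); compass angle measured from north
  aspect <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  flat <- !is.na(slope) & slope == 0
  aspect[flat] <- FLAT_ASPECT
  list(slope = grid_raster(slope, depth$cell_size, depth$origin, "degrees"),
       aspect = grid_raster(aspect, depth$cell_size, depth$origin, "degrees"))
}

#' Decompose aspect into northness and eastness
#'
#' northness = cos(aspect), eastness = sin(aspect), with aspect in degrees.
#' Flat-sentinel cells get 0 for both components so the sentinel never leaks
#' into trigonometry.
#'
#' @param aspect aspect [grid_raster] from [compute_slope_aspect()].
#' @return list with [grid_raster] elements `northness` and `eastness`.
#' @export
aspect_to_components <- function(aspect) {
  stopifnot(is_grid_raster(aspect))
  a <- aspect$values
  rad <- a * pi / 180
  n <- cos(rad); e <- sin(rad)
  flat <- !is.na(a) & a == FLAT_ASPECT
  n[flat] <- 0; e[flat] <- 0
  list(northness = grid_raster(n, aspect$cell_size, aspect$origin),
       eastness = grid_raster(e, aspect$cell_size, aspect$origin))
}

#' Mean curvature of a depth raster
#'
#' Zevenbergen-Thorne quadratic-surface curvature: minus the mean of the two
#' unmixed second derivatives of elevation (= negative depth), scaled by
#' `params$curvature_scale` (default per 100 m). Positive values are
#' convex-up (crests and shoal tops), negative concave-up (troughs).
#'
#' @inheritParams compute_slope_aspect
#' @param params a [terrain_params()] list.
#' @return a curvature [grid_raster].
#' @export
compute_mean_curvature <- function(depth, params = terrain_params()) {
  stopifnot(is_grid_raster(depth))
  if (all(is.na(depth$values)))
    stop("depth raster has no valid cells", call. = FALSE)
  z <- -depth$values
  cs <- depth$cell_size
  zxx <- (shift_matrix(z, 0L, -1L) - 2 * z + shift_matrix(z, 0L, 1L)) / cs^2
  zyy <- (shift_matrix(z, -1L, 0L) - 2 * z + shift_matrix(z, 1L, 0L)) / cs^2
  curv <- -params$curvature_scale * (zxx + zyy) / 2
  curv[is.na(z)] <- NA
  grid_raster(curv, cs, depth$origin, sprintf("1/(%gm)", params$curvature_scale))
}

#' Vector ruggedness measure
#'
#' Per cell, unit surface normals n = (sin S sin A, sin S cos A, cos S) are
#' summed over the `vrm_window` x `vrm_window` neighborhood; VRM is one minus
#' the resultant magnitude normalized by the count of valid cells in the
#' window. 0 on any plane, approaching 1 for maximally disordered normals.
#' Flat-sentinel cells contribute the vertical normal (0, 0, 1).
#'
#' @param slope,aspect layers from [compute_slope_aspect()].
#' @param params a [terrain_params()] list.
#' @return a VRM [grid_raster] with values in \[0, 1\].
#' @export
compute_vrm <- function(slope, aspect, params = terrain_params()) {
  stopifnot(is_grid_raster(slope), is_grid_raster(aspect))
  stopifnot_same_geom(slope, aspect, "slope/aspect")
  w <- params$vrm_window
  if (w > min(dim(slope$values)))
    stop("`vrm_window` exceeds the grid size", call. = FALSE)
  s <- slope$values * pi / 180
  a <- aspect$values * pi / 180
  flat <- !is.na(aspect$values) & aspect$values == FLAT_ASPECT
  x <- sin(s) * sin(a); y <- sin(s) * cos(a); z <- cos(s)
  x[flat] <- 0; y[flat] <- 0; z[flat] <- 1
  half <- (w - 1L) %/% 2L
  sum_win <- function(m) {
    valid <- !is.na(m)
    m[!valid] <- 0
    tot <- matrix(0, nrow(m), ncol(m)); n <- tot
    for (di in -half:half) for (dj in -half:half) {
      tot <- tot + shift_zero(m, di, dj)
      n <- n + shift_zero(valid * 1, di, dj)
    }
    list(tot = tot, n = n)
  }
  sx <- sum_win(x); sy <- sum_win(y); sz <- sum_win(z)
  n_valid <- sx$n
  res <- sqrt(sx$tot^2 + sy$tot^2 + sz$tot^2)
  vrm <- 1 - res / n_valid
  vrm[n_valid == 0] <- NA
  vrm[is.na(s)] <- NA
  vrm <- pmin(pmax(vrm, 0), 1)   # clamp tiny negative rounding noise
  grid_raster(vrm, slope$cell_size, slope$origin)
}

# zero-padded shift (window sums treat off-grid as absent, not NA)
shift_zero <- function(m, di, dj) {
  out <- shift_matrix(m, di, dj)
  out[is.na(out)] <- 0
  out
}

# Ten-form geomorphon lookup, indexed by [count of "-" + 1, count of "+" + 1]
# ("+" = a direction whose maximum line-of-sight angle is upward beyond the
# flatness angle, "-" downward). Forms: FL flat, PK peak, RI ridge,
# SH shoulder, SP spur, SL slope, HL hollow, FS footslope, VL valley, PT pit.
geomorphon_lut10 <- function() {
  t(matrix(c(
    # plus:  0     1     2     3     4     5     6     7     8      minus:
    "FL", "FL", "FL", "FS", "FS", "VL", "VL", "VL", "PT",         # 0
    "FL", "FL", "FS", "FS", "FS", "VL", "VL", "VL", NA,           # 1
    "FL", "SH", "SL", "SL", "HL", "HL", "VL", NA, NA,             # 2
    "SH", "SH", "SL", "SL", "SL", "HL", NA, NA, NA,               # 3
    "SH", "SH", "SP", "SL", "SL", NA, NA, NA, NA,                 # 4
    "RI", "RI", "SP", "SP", NA, NA, NA, NA, NA,                   # 5
    "RI", "RI", "RI", NA, NA, NA, NA, NA, NA,                     # 6
    "RI", "RI", NA, NA, NA, NA, NA, NA, NA,                       # 7
    "PK", NA, NA, NA, NA, NA, NA, NA, NA                          # 8
  ), nrow = 9L))
}

#' Geomorphon form names and integer codes
#'
#' The six collapsed landform classes used as categorical predictors. The
#' ten-form classification collapses as peak and spur to ridge, pit and
#' hollow to valley.
#' @export
GEOMORPHON_FORMS <- c(flat = 1L, ridge = 2L, shoulder = 3L, slope = 4L,
                      footslope = 5L, valley = 6L)

collapse_form <- function(f) {
  switch(f,
         FL = "flat", PK = "ridge", RI = "ridge", SP = "ridge",
         SH = "shoulder", SL = "slope", FS = "footslope",
         HL = "valley", VL = "valley", PT = "valley")
}

#' Geomorphon landform classification
#'
#' Per cell, the maximum upward and maximum downward line-of-sight angles to
#' cells within `geomorphon_lookup` steps are found in each of the 8 compass
#' directions (on elevation = negative depth, so "ridge" means a shoal
#' crest). Each direction is coded + / 0 / - by comparing the dominant angle
#' against `flatness_angle`; the (+, -) count pair indexes the standard
#' ten-form landform table, collapsed to six forms (flat, ridge, shoulder,
#' slope, footslope, valley). When the upward and downward angles tie above
#' the flatness angle the direction codes "+".
#'
#' @inheritParams compute_mean_curvature
#' @return a [grid_raster] of integer codes per [GEOMORPHON_FORMS].
#' @export
compute_geomorphons <- function(depth, params = terrain_params()) {
  stopifnot(is_grid_raster(depth))
  z <- -depth$values
  cs <- depth$cell_size
  L <- params$geomorphon_lookup
  t_ang <- params$flatness_angle
  dirs <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  n_plus <- matrix(0, nrow(z), ncol(z))
  n_minus <- n_plus
  for (d in dirs) {
    up <- matrix(-Inf, nrow(z), ncol(z))
    dn <- up
    for (k in seq_len(L)) {
      zk <- shift_matrix(z, d[1] * k, d[2] * k)
      dist <- k * cs * sqrt(sum(d^2))
      ang <- atan2(zk - z, dist) * 180 / pi
      ok <- !is.na(ang)
      up[ok] <- pmax(up[ok], ang[ok])
      dn[ok] <- pmax(dn[ok], -ang[ok])
    }
    # directions with no visible relief (off-grid or nodata throughout, or
    # everything inside the flatness angle) code level
    plus <- up > t_ang & up >= dn
    minus <- !plus & dn > t_ang
    n_plus <- n_plus + plus
    n_minus <- n_minus + minus
  }
  lut <- geomorphon_lut10()
  forms10 <- lut[cbind(as.vector(n_minus) + 1L, as.vector(n_plus) + 1L)]
  codes <- GEOMORPHON_FORMS[vapply(forms10, collapse_form, "")]
  codes[as.vector(is.na(z))] <- NA
  grid_raster(matrix(as.numeric(codes), nrow(z), ncol(z)),
              cs, depth$origin, "class")
}

#' One-hot encode a geomorphon raster
#'
#' @param gm geomorphon code [grid_raster] from [compute_geomorphons()].
#' @return named list of six 0/1 [grid_raster]s (`flat`, `ridge`, `shoulder`,
#'   `slope`, `footslope`, `valley`); on every valid cell exactly one is 1.
#' @export
one_hot_geomorphons <- function(gm) {
  stopifnot(is_grid_raster(gm))
  v <- gm$values
  known <- v[!is.na(v)]
  if (length(known) && !all(known %in% GEOMORPHON_FORMS))
    stop("unknown geomorphon class code", call. = FALSE)
  out <- lapply(names(GEOMORPHON_FORMS), function(nm) {
    grid_raster((v == GEOMORPHON_FORMS[[nm]]) * 1,
                gm$cell_size, gm$origin)
  })
  names(out) <- names(GEOMORPHON_FORMS)
  out
}

#' All bathymetry-derived predictor layers at analysis resolution
#'
#' Convenience wrapper: slope, aspect components, mean curvature, VRM and
#' one-hot geomorphons computed at the fine resolution of `depth`, then each
#' aggregated to `coarse_cell_size` (mean for continuous layers, majority
#' for the six indicator layers). Depth itself is aggregated alongside.
#'
#' @inheritParams compute_mean_curvature
#' @param coarse_cell_size analysis resolution in meters.
#' @return named list of coarse [grid_raster]s: `depth`, `slope`,
#'   `curvature`, `northness`, `eastness`, `vrm`, and `gm_*` indicators.
#' @export
terrain_predictors <- function(depth, coarse_cell_size,
                               params = terrain_params()) {
  sa <- compute_slope_aspect(depth)
  ne <- aspect_to_components(sa$aspect)
  curv <- compute_mean_curvature(depth, params)
  vrm <- compute_vrm(sa$slope, sa$aspect, params)
  gm <- compute_geomorphons(depth, params)
  oh <- one_hot_geomorphons(gm)
  cont <- list(depth = depth, slope = sa$slope, curvature = curv,
               northness = ne$northness, eastness = ne$eastness, vrm = vrm)
  out <- lapply(cont, aggregate_to_coarse,
                coarse_cell_size = coarse_cell_size, method = "mean")
  for (nm in names(oh))
    out[[paste0("gm_", nm)]] <- aggregate_to_coarse(oh[[nm]], coarse_cell_size,
                                                    method = "majority")
  out
}
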