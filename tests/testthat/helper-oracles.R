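# Independent brute-force per-cell oracles for the terrain operations.
# These deliberately avoid the vectorized shift-based code paths in the
# package: everything is computed cell by cell with explicit loops, and the
# curvature oracle goes through an exact 9-term polynomial solve instead of
# finite differences.

oracle_slope_aspect <- function(depth_mat, cs) {
  z <- -depth_mat
  nr <- nrow(z); nc <- ncol(z)
  slope <- matrix(NA_real_, nr, nc)
  aspect <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    gx <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
             (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * cs)
    gy <- ((w[1, 1] + 2 * w[1, 2] + w[1, 3]) -
             (w[3, 1] + 2 * w[3, 2] + w[3, 3])) / (8 * cs)
    slope[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    if (gx == 0 && gy == 0) {
      aspect[i, j] <- FLAT_ASPECT
    } else {
      a <- atan2(-gx, -gy) * 180 / pi
      aspect[i, j] <- (a + 360) %% 360
    }
  }
  list(slope = slope, aspect = aspect)
}

# Exact 9-term quadric through the 3x3 window (Zevenbergen-Thorne surface);
# mean curvature from its second-derivative coefficients.
oracle_mean_curvature <- function(depth_mat, cs, scale = 100) {
  z <- -depth_mat
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  xs <- c(-cs, 0, cs)
  design <- NULL
  for (dy in c(cs, 0, -cs)) for (dx in xs)
    design <- rbind(design, c(dx^2 * dy^2, dx^2 * dy, dx * dy^2, dx^2,
                              dy^2, dx * dy, dx, dy, 1))
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    zz <- as.vector(t(w))            # row-major: y = +cs row first
    coefs <- solve(design, zz)
    D <- coefs[4]; E <- coefs[5]     # z_xx = 2D, z_yy = 2E at the center
    out[i, j] <- -scale * (D + E)
  }
  out
}

oracle_vrm <- function(slope_mat, aspect_mat, window) {
  nr <- nrow(slope_mat); nc <- ncol(slope_mat)
  half <- (window - 1) %/% 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(slope_mat[i, j])) next
    sx <- sy <- sz <- 0; n <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      s <- slope_mat[ii, jj]; a <- aspect_mat[ii, jj]
      if (is.na(s) || is.na(a)) next
      if (a == FLAT_ASPECT) {
        sz <- sz + 1
      } else {
        sr <- s * pi / 180; ar <- a * pi / 180
        sx <- sx + sin(sr) * sin(ar)
        sy <- sy + sin(sr) * cos(ar)
        sz <- sz + cos(sr)
      }
      n <- n + 1
    }
    if (n > 0) out[i, j] <- 1 - sqrt(sx^2 + sy^2 + sz^2) / n
  }
  pmin(pmax(out, 0), 1)
}

# oracle's own copy of the ten-form table and six-form collapse
oracle_gm_form <- function(n_plus, n_minus) {
  lut <- matrix(NA_character_, 9, 9)  # [minus + 1, plus + 1]
  lut[1, ] <- c("flat", "flat", "flat", "footslope", "footslope",
                "valley", "valley", "valley", "valley")      # pit -> valley
  lut[2, 1:8] <- c("flat", "flat", "footslope", "footslope", "footslope",
                   "valley", "valley", "valley")
  lut[3, 1:7] <- c("flat", "shoulder", "slope", "slope", "valley",
                   "valley", "valley")                       # hollow -> valley
  lut[4, 1:6] <- c("shoulder", "shoulder", "slope", "slope", "slope",
                   "valley")
  lut[5, 1:5] <- c("shoulder", "shoulder", "ridge", "slope", "slope")
  lut[6, 1:4] <- c("ridge", "ridge", "ridge", "ridge")       # spur -> ridge
  lut[7, 1:3] <- c("ridge", "ridge", "ridge")
  lut[8, 1:2] <- c("ridge", "ridge")
  lut[9, 1] <- "ridge"                                       # peak -> ridge
  lut[n_minus + 1, n_plus + 1]
}

oracle_geomorphons <- function(depth_mat, cs, lookup, flat_angle) {
  z <- -depth_mat
  nr <- nrow(z); nc <- ncol(z)
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) next
    np <- nm <- 0
    for (d in seq_len(8)) {
      up <- -Inf; dn <- -Inf
      for (k in seq_len(lookup)) {
        ii <- i + dirs[d, 1] * k; jj <- j + dirs[d, 2] * k
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) break
        if (is.na(z[ii, jj])) next
        dist <- k * cs * sqrt(sum(dirs[d, ]^2))
        ang <- atan2(z[ii, jj] - z[i, j], dist) * 180 / pi
        up <- max(up, ang); dn <- max(dn, -ang)
      }
      if (up > flat_angle && up >= dn) np <- np + 1
      else if (dn > flat_angle) nm <- nm + 1
    }
    out[i, j] <- GEOMORPHON_FORMS[[oracle_gm_form(np, nm)]]
  }
  out
}
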