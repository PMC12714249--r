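#' Lightweight planar grid raster
#'
#' A minimal single-band raster: a numeric matrix plus planar georeferencing
#' (square cell size and the x/y coordinates of the lower-left corner).
#' Rows run north to south (row 1 is the northernmost), columns west to east,
#' matching the usual on-disk raster layout. Missing cells are `NA`
#' internally; a nodata sentinel is only used on disk.
#'
#' @param values numeric matrix of cell values (row 1 = north edge).
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, planar x/y of the lower-left grid corner.
#' @param units free-text unit label carried along for display.
#' @return an object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(1:12, 3, 4), cell_size = 30)
#' dim(r)
#' @export
grid_raster <- function(values, cell_size, origin = c(0, 0), units = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L) stop("`origin` must have length 2", call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), units = units),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  n_na <- sum(is.na(x$values))
  cat(sprintf("grid_raster: %d x %d cells @ %g m", d[1], d[2], x$cell_size))
  if (nzchar(x$units)) cat(sprintf(" [%s]", x$units))
  cat(sprintf("\n  origin (%g, %g); %d nodata cell%s\n",
              x$origin[1], x$origin[2], n_na, if (n_na == 1) "" else "s"))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

is_grid_raster <- function(x) inherits(x, "grid_raster")

stopifnot_same_geom <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s are not co-registered (shape mismatch)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read / write Esri ASCII grid files
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows` header,
#' then rows north to south). Values equal to the nodata sentinel become
#' `NA` on read and vice versa on write.
#'
#' @param path file path.
#' @param x a [grid_raster].
#' @param nodata sentinel written for `NA` cells.
#' @return `read_ascii_grid` returns a [grid_raster]; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(p) p)
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header", call. = FALSE)
  body <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(body, nrow = vals["nrows"], ncol = vals["ncols"], byrow = TRUE)
  if ("nodata_value" %in% keys) m[m == vals["nodata_value"]] <- NA_real_
  grid_raster(m, cell_size = vals["cellsize"],
              origin = c(vals["xllcorner"], vals["yllcorner"]))
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(is_grid_raster(x))
  v <- x$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", x$origin[2]),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Aggregate a fine raster to a coarser cell size
#'
#' Each coarse cell collects every fine cell whose center falls inside it
#' (so non-integer resolution ratios, e.g. 4 m to 30 m, are supported).
#' Continuous layers take the mean of valid fine cells; indicator (one-hot)
#' layers take the majority, with a fraction of exactly 0.5 rounding up to 1.
#' Coarse cells containing no valid fine cell are nodata.
#'
#' @param x a fine-resolution [grid_raster].
#' @param coarse_cell_size target cell size in meters, larger than
#'   `x$cell_size`.
#' @param method `"mean"` for continuous layers, `"majority"` for 0/1 layers.
#' @return a [grid_raster] at the coarse resolution, sharing `x`'s origin.
#' @export
aggregate_to_coarse <- function(x, coarse_cell_size,
                                method = c("mean", "majority")) {
  stopifnot(is_grid_raster(x))
  method <- match.arg(method)
  if (coarse_cell_size <= x$cell_size)
    stop("`coarse_cell_size` must exceed the fine cell size", call. = FALSE)
  fr <- nrow(x$values); fc <- ncol(x$values); cs <- x$cell_size
  # fine-cell center offsets from the grid's top-left corner
  cx <- (seq_len(fc) - 0.5) * cs
  cy <- (seq_len(fr) - 0.5) * cs            # measured downward from the top
  col_g <- floor(cx / coarse_cell_size) + 1L
  row_g <- floor(cy / coarse_cell_size) + 1L
  nr <- max(row_g); nc <- max(col_g)
  idx <- (rep(col_g, each = fr) - 1L) * nr + rep(row_g, times = fc)
  v <- as.vector(x$values)
  ok <- !is.na(v)
  sums <- rowsum(v[ok], idx[ok])
  cnts <- rowsum(rep(1, sum(ok)), idx[ok])
  out <- rep(NA_real_, nr * nc)
  out[as.integer(rownames(sums))] <- sums / cnts
  if (method == "majority") out <- ifelse(is.na(out), NA_real_,
                                          as.numeric(out >= 0.5))
  top_y <- x$origin[2] + fr * cs
  grid_raster(matrix(out, nr, nc),
              cell_size = coarse_cell_size,
              origin = c(x$origin[1], top_y - nr * coarse_cell_size),
              units = x$units)
}

# Shift a matrix by (di, dj) cells, padding with NA. di > 0 pulls values
# from rows further down (southwards), dj > 0 from columns further east.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di
  cj <- seq_len(nc) + dj
  ok_r <- ri >= 1L & ri <= nr
  ok_c <- cj >= 1L & cj <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
  out
}

# Separable repeated box blur; cheap stand-in for Gaussian smoothing of
# white-noise fields. Edge cells renormalize by the in-grid kernel mass.
smooth_field <- function(m, half_width, passes = 3L) {
  blur1d <- function(v, w) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - w, 1L)
    hi <- pmin(seq_len(n) + w, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  for (k in seq_len(passes)) {
    m <- apply(m, 2L, blur1d, w = half_width)
    m <- t(apply(m, 1L, blur1d, w = half_width))
  }
  m
}
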