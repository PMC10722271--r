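#' Lightweight in-memory raster grid
#'
#' A `raster_grid` is a regular, axis-aligned grid of cell values in a
#' projected coordinate system (meters). Row 1 is the northernmost row;
#' missing cells are `NA`. All spatial stages of the pipeline exchange
#' rasters in this container.
#'
#' @param values numeric matrix of cell values; `values[1, 1]` is the
#'   north-west cell.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cell_size cell edge length in meters (cells are square).
#' @param crs optional free-text CRS tag carried through unchanged.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cell_size = 20, crs = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cell_size = cell_size, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols @ %g m\n", nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cell_size,
              x$ymin, x$ymin + nrow(v) * x$cell_size))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

raster_ymax <- function(grid) grid$ymin + nrow(grid$values) * grid$cell_size
raster_xmax <- function(grid) grid$xmin + ncol(grid$values) * grid$cell_size

#' Coordinates of every cell center
#'
#' @param grid a `raster_grid`.
#' @return data.frame with columns `row`, `col`, `x`, `y` in row-major order.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  xs <- grid$xmin + (seq_len(nc) - 0.5) * cs
  ys <- raster_ymax(grid) - (seq_len(nr) - 0.5) * cs
  data.frame(
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), times = nr),
    x = rep(xs, times = nr),
    y = rep(ys, each = nc)
  )
}

#' Row/column of the cell containing a point
#'
#' Points on an internal cell boundary belong to the cell to the east/south
#' (half-open cells). Returns NA row/col for points outside the extent.
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates (m), vectorized.
#' @return data.frame with columns `row`, `col`.
#' @export
cell_at_xy <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$xmin) / cs) + 1L
  row <- floor((raster_ymax(grid) - y) / cs) + 1L
  # points exactly on the top or right edge still belong to the grid
  col[x == raster_xmax(grid)] <- ncol(grid$values)
  row[y == grid$ymin] <- nrow(grid$values)
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract cell values at point locations
#'
#' @inheritParams cell_at_xy
#' @return numeric vector, NA for points outside the grid.
#' @export
extract_xy <- function(grid, x, y) {
  rc <- cell_at_xy(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every GIS. NA cells are written
#' as the `nodata` marker.
#'
#' @param grid a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata numeric nodata marker written to the header.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 15, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any GIS.
#' @return a `raster_grid` with nodata cells as NA.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == val[["nrows"]], ncol(v) == val[["ncols"]])
  v[v == val[["nodata_value"]]] <- NA_real_
  raster_grid(v, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              cell_size = val[["cellsize"]])
}

#' Smooth a raster with a Gaussian kernel
#'
#' Separable convolution with reflected edges. Used by the synthetic
#' landscape generator to impose a spatial correlation length on white
#' noise; `sigma_cells = 0` leaves the raster untouched.
#'
#' @param grid a `raster_grid` (no NA cells).
#' @param sigma_cells kernel standard deviation in cell units.
#' @return smoothed `raster_grid` on the same grid.
#' @export
gaussian_smooth <- function(grid, sigma_cells) {
  if (sigma_cells < 0) stop("sigma_cells must be nonnegative")
  if (sigma_cells == 0) return(grid)
  r <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-r, r), sd = sigma_cells)
  k <- k / sum(k)
  v <- grid$values
  v <- apply(v, 2L, convolve_reflect, kernel = k)        # down columns
  v <- t(apply(v, 1L, convolve_reflect, kernel = k))     # across rows
  raster_grid(v, grid$xmin, grid$ymin, grid$cell_size, grid$crs)
}

convolve_reflect <- function(x, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- length(x)
  idx <- seq(-r + 1L, n + r)
  # reflect indices at both ends (period-free mirror)
  idx[idx < 1L] <- 2L - idx[idx < 1L]
  idx[idx > n] <- 2L * n - idx[idx > n]
  xp <- x[idx]
  stats::filter(xp, kernel, sides = 2L)[(r + 1L):(r + n)]
}

#' Slope and aspect from a digital elevation model
#'
#' Horn's 3x3 finite-difference stencil. Slope is returned in degrees;
#' aspect in degrees clockwise from north, with flat cells (zero gradient)
#' assigned -1. Border cells use reflected neighbors.
#'
#' @param dem a `raster_grid` of elevations (m).
#' @return list with `slope` and `aspect` rasters on the same grid.
#' @export
terrain_slope_aspect <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  cs <- dem$cell_size
  up    <- z[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- z[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  shift_l <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  shift_r <- function(m) m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  a <- shift_l(up);   b <- up;   cc <- shift_r(up)
  d <- shift_l(z);               f <- shift_r(z)
  g <- shift_l(down); h <- down; i <- shift_r(down)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)   # y increases north
  dzdy <- -dzdy
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # downslope direction, clockwise from north
  aspect <- (atan2(dzdx, dzdy) * 180 / pi + 180) %% 360
  aspect[dzdx == 0 & dzdy == 0] <- -1
  list(
    slope = raster_grid(slope, dem$xmin, dem$ymin, cs, dem$crs),
    aspect = raster_grid(aspect, dem$xmin, dem$ymin, cs, dem$crs)
  )
}

#' Resample a raster onto a template grid by bilinear interpolation
#'
#' Each template cell center is interpolated from the four surrounding
#' source cell centers; beyond the outermost ring of source centers the
#' fractional position is clamped (edge extension). Template cells whose
#' center falls outside the source extent, or with any NA contributor,
#' become NA.
#'
#' @param raster source `raster_grid`.
#' @param template `raster_grid` defining the output geometry.
#' @return `raster_grid` on the template grid.
#' @export
resample_bilinear <- function(raster, template) {
  if (raster$xmin >= raster_xmax(template) || raster_xmax(raster) <= template$xmin ||
      raster$ymin >= raster_ymax(template) || raster_ymax(raster) <= template$ymin)
    stop("source raster and template extents are disjoint")
  src <- raster$values
  nr <- nrow(src); nc <- ncol(src)
  cs <- raster$cell_size
  ctr <- cell_centers(template)
  inside <- ctr$x >= raster$xmin & ctr$x <= raster_xmax(raster) &
            ctr$y >= raster$ymin & ctr$y <= raster_ymax(raster)
  # fractional (row, col) position in source cell-center coordinates
  fc <- (ctr$x - raster$xmin) / cs + 0.5
  fr <- (raster_ymax(raster) - ctr$y) / cs + 0.5
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1L); c0[nc == 1L] <- 1L
  r0 <- pmin(floor(fr), nr - 1L); r0[nr == 1L] <- 1L
  c1 <- pmin(c0 + 1L, nc); r1 <- pmin(r0 + 1L, nr)
  wx <- fc - c0; wy <- fr - r0
  v00 <- src[cbind(r0, c0)]; v01 <- src[cbind(r0, c1)]
  v10 <- src[cbind(r1, c0)]; v11 <- src[cbind(r1, c1)]
  out <- (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
  out[!inside] <- NA_real_
  raster_grid(matrix(out, nrow(template$values), ncol(template$values), byrow = TRUE),
              template$xmin, template$ymin, template$cell_size, template$crs)
}
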