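## Raster grids are plain numeric matrices on a shared lattice. Row i maps to
## y = y0 + (i - 0.5) * cell_size, column j to x = x0 + (j - 0.5) * cell_size,
## i.e. row 1 is the southern edge; TIFF export flips to the usual north-up
## order. All coordinates are projected meters.

grid_xy <- function(nr, nc, cell_size, x0 = 0, y0 = 0) {
  list(
    x = x0 + (seq_len(nc) - 0.5) * cell_size,
    y = y0 + (seq_len(nr) - 0.5) * cell_size
  )
}

#' Nearest-cell raster lookup at point coordinates
#'
#' @param grid numeric matrix (see package conventions for orientation).
#' @param cell_size cell edge length in meters.
#' @param x,y numeric vectors of projected coordinates (meters).
#' @param x0,y0 coordinates of the grid's lower-left corner.
#' @return numeric vector of cell values; points outside the grid give `NA`.
#' @export
extract_at <- function(grid, cell_size, x, y, x0 = 0, y0 = 0) {
  stopifnot(is.matrix(grid), cell_size > 0, length(x) == length(y))
  j <- ceiling((x - x0) / cell_size)
  i <- ceiling((y - y0) / cell_size)
  ok <- i >= 1 & i <= nrow(grid) & j >= 1 & j <= ncol(grid) &
    is.finite(i) & is.finite(j)
  out <- rep(NA_real_, length(x))
  out[ok] <- grid[cbind(i[ok], j[ok])]
  out
}

## Smooth mean-zero unit-variance random field: white noise convolved with a
## Gaussian kernel (circular, via FFT). `wavelength` is in cells and sets the
## kernel sd to wavelength/4.
smooth_field <- function(nr, nc, wavelength) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  sigma <- max(wavelength / 4, 0.5)
  dx <- seq_len(nr) - 1; dx <- pmin(dx, nr - dx)
  dy <- seq_len(nc) - 1; dy <- pmin(dy, nc - dy)
  K <- exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
  K <- K / sum(K)
  f <- Re(fft(fft(z) * fft(K), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(as.vector(f))
}

## Deterministic-looking smooth surface: low-order harmonics with seeded
## random amplitudes/phases blended with a seeded smooth noise field, then
## normalized to max |.| = 1 so callers control amplitude exactly.
harmonic_field <- function(nr, nc, wavelength_cells) {
  u <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc) / nc
  v <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc) / nr
  f <- matrix(0, nr, nc)
  modes <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1), c(2, 1))
  for (m in modes) {
    a <- rnorm(1); ph <- runif(1, 0, 2 * pi)
    f <- f + a * sin(2 * pi * (m[1] * u + m[2] * v) + ph)
  }
  f <- f / max(1e-12, stats::sd(as.vector(f)))
  g <- 0.7 * f + 0.3 * smooth_field(nr, nc, wavelength_cells)
  g / max(abs(g))
}

#' Clamp values to the unit interval
#'
#' Canopy closure is a proportion; every FCC-valued output is clamped with
#' this helper. Matrix dimensions are preserved.
#'
#' @param x numeric vector or matrix.
#' @return `x` with values forced into \[0, 1\].
#' @export
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# x first: pmin/pmax take attributes (matrix dims) from their first argument
clamp_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

standardize_grid <- function(g) (g - mean(g)) / stats::sd(as.vector(g))

#' Write a grid to TIFF with a JSON georeferencing sidecar
#'
#' Writes a single-band 32-bit float TIFF (north-up) plus `<path>.json`
#' holding the cell size, lower-left origin and EPSG code, so the grid can be
#' re-imported losslessly with [read_grid_tiff()].
#'
#' @param grid numeric matrix.
#' @param path output file path (`.tif`).
#' @param cell_size,x0,y0,epsg georeferencing fields stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_grid_tiff <- function(grid, path, cell_size, x0 = 0, y0 = 0, epsg = NA) {
  img <- grid[rev(seq_len(nrow(grid))), , drop = FALSE]
  # TIFF samples live in [0, 1]; rescale and record the affine in the sidecar
  rng <- range(img, finite = TRUE)
  scale <- max(rng[2] - rng[1], 1)
  offset <- min(rng[1], 0)
  if (rng[1] < 0 || rng[2] > 1) {
    offset <- rng[1]
    img <- (img - offset) / scale
  } else {
    scale <- 1; offset <- 0
  }
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(nrow = nrow(grid), ncol = ncol(grid), cell_size = cell_size,
               x0 = x0, y0 = y0, epsg = epsg, order = "south-up matrix",
               value_scale = scale, value_offset = offset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_tiff
#' @export
read_grid_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  g <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$value_scale))
      g <- g * meta$value_scale + meta$value_offset
    attr(g, "cell_size") <- meta$cell_size
    attr(g, "x0") <- meta$x0; attr(g, "y0") <- meta$y0
    attr(g, "epsg") <- meta$epsg
  }
  g
}
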