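#' Vegetation indices from reflectance grids
#'
#' Computes the standard optical vegetation indices from co-registered
#' reflectance grids. Formulas are the conventional definitions: NDVI =
#' (NIR - Red)/(NIR + Red), GNDVI = (NIR - Green)/(NIR + Green), DVI =
#' NIR - Red, SAVI with L = 0.5, OSAVI with 0.16, EVI with G = 2.5, C1 = 6,
#' C2 = 7.5, L = 1 (requires a blue band), EVI2 = 2.5 (NIR - Red)/(NIR +
#' 2.4 Red + 1), RVI = NIR/Red, MSAVI by the inverted quadratic, GRVI =
#' NIR/Green, RDVI = (NIR - Red)/sqrt(NIR + Red). IDVI has no standard
#' definition and defaults to 1 + NDVI (configurable via `idvi_fun`).
#' Zero denominators yield `NA` (nodata), never an error.
#'
#' @param bands named list of reflectance matrices; `red` and `nir` are
#'   required, `green` and `blue` enable the green/blue-band indices.
#' @param which character vector of index names to compute.
#' @param idvi_fun function of `(nir, red)` grids giving the IDVI variant.
#' @return named list of index matrices.
#' @export
compute_indices <- function(bands,
                            which = c("NDVI", "GNDVI", "DVI", "SAVI", "OSAVI",
                                      "EVI", "EVI2", "RVI", "MSAVI", "GRVI",
                                      "RDVI", "IDVI"),
                            idvi_fun = function(nir, red) 1 + safe_div(nir - red, nir + red)) {
  need <- function(b) {
    if (is.null(bands[[b]])) stop(sprintf("missing band '%s'", b), call. = FALSE)
    bands[[b]]
  }
  R <- need("red"); N <- need("nir")
  out <- list()
  for (ix in which) {
    out[[ix]] <- switch(
      ix,
      NDVI  = safe_div(N - R, N + R),
      GNDVI = { G <- need("green"); safe_div(N - G, N + G) },
      DVI   = N - R,
      SAVI  = 1.5 * safe_div(N - R, N + R + 0.5),
      OSAVI = safe_div(N - R, N + R + 0.16),
      EVI   = { B <- need("blue"); 2.5 * safe_div(N - R, N + 6 * R - 7.5 * B + 1) },
      EVI2  = 2.5 * safe_div(N - R, N + 2.4 * R + 1),
      RVI   = safe_div(N, R),
      MSAVI = (2 * N + 1 - sqrt(pmax(0, (2 * N + 1)^2 - 8 * (N - R)))) / 2,
      GRVI  = { G <- need("green"); safe_div(N, G) },
      RDVI  = safe_div(N - R, sqrt(pmax(0, N + R))),
      IDVI  = idvi_fun(N, R),
      stop(sprintf("unknown index '%s'", ix), call. = FALSE)
    )
  }
  out
}

safe_div <- function(num, den) {
  out <- num / den
  out[abs(den) < 1e-12] <- NA_real_
  out
}

#' SAR backscatter transforms
#'
#' The dB difference `VV - VH` and the linear power ratio `VV/VH =
#' 10^((vv_db - vh_db)/10)`. The difference is kept on the dB scale; the
#' ratio is computed on linear powers, where it is physically meaningful.
#'
#' @param vv_db,vh_db backscatter grids in dB, same shape.
#' @return list with `VV_minus_VH` (dB) and `VV_over_VH` (linear ratio).
#' @export
sar_transforms <- function(vv_db, vh_db) {
  if (!all(dim(vv_db) == dim(vh_db))) stop("VV and VH grids differ in shape")
  d <- vv_db - vh_db
  list(VV_minus_VH = d, VV_over_VH = 10^(d / 10))
}

#' Terrain derivatives from a DEM
#'
#' Slope and aspect by Horn's 3x3 finite differences (the method used by
#' standard GIS raster tools), plus the elevation passthrough. Edges are
#' mirror-padded so outputs keep the DEM's shape. Aspect is in compass
#' degrees (0 = north, clockwise); cells with zero gradient get the flat
#' sentinel `-1`.
#'
#' @param dem elevation grid, meters.
#' @param cell_size cell edge length, meters.
#' @param flat_tol gradient magnitude below which a cell counts as flat.
#' @return list with `slope` (degrees), `aspect` (degrees or -1), `elevation`.
#' @export
terrain_derivatives <- function(dem, cell_size, flat_tol = 1e-9) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (nrow(dem) < 3 || ncol(dem) < 3) stop("DEM must be at least 3x3")
  p <- mirror_pad(dem, 1)
  nr <- nrow(dem); nc <- ncol(dem)
  sh <- function(di, dj) p[(1 + di):(nr + di), (1 + dj):(nc + dj)]
  # neighbours (rows increase northward in this package's grid convention)
  nw <- sh(2, 0); n_ <- sh(2, 1); ne <- sh(2, 2)
  w_ <- sh(1, 0);                 e_ <- sh(1, 2)
  sw <- sh(0, 0); s_ <- sh(0, 1); se <- sh(0, 2)
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cell_size)
  dzdy <- ((ne + 2 * n_ + nw) - (se + 2 * s_ + sw)) / (8 * cell_size)
  grad <- sqrt(dzdx^2 + dzdy^2)
  slope <- atan(grad) * 180 / pi
  aspect <- (atan2(dzdx, dzdy) * 180 / pi + 180) %% 360  # downslope direction
  aspect[grad < flat_tol] <- -1
  list(slope = slope, aspect = aspect, elevation = dem)
}

mirror_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci, drop = FALSE]
}

#' Sliding-window GLCM texture features
#'
#' For each pixel, the surrounding `window` x `window` neighbourhood
#' (mirror-padded at edges) is min-max quantized to `levels` gray levels, a
#' symmetric normalized co-occurrence matrix is accumulated over the given
#' offsets at distance `step`, and the eight Haralick-type statistics are
#' emitted: mean (ME), variance (VA), homogeneity (HO), contrast (CO),
#' dissimilarity (DI), entropy (EN, natural log), angular second moment (SM)
#' and correlation (CR). A constant window yields the closed-form extremes
#' (CO = DI = EN = 0, SM = HO = 1) and `NA` correlation.
#'
#' @param band numeric grid.
#' @param window odd window size (default 5).
#' @param step co-occurrence offset distance in pixels (default 1).
#' @param levels number of gray levels (default 64).
#' @param offsets integer matrix of offset directions (rows `c(drow, dcol)`);
#'   default averages the four standard directions 0, 45, 90, 135 degrees.
#' @return named list of eight matrices (`ME`, `VA`, `HO`, `CO`, `DI`, `EN`,
#'   `SM`, `CR`), each the band's shape.
#' @export
glcm_features <- function(band, window = 5, step = 1, levels = 64,
                          offsets = NULL) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (levels < 2) stop("levels must be >= 2")
  if (nrow(band) < window || ncol(band) < window)
    stop("grid too small for the texture window")
  if (is.null(offsets))
    offsets <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  offsets <- matrix(as.integer(offsets * step), ncol = 2)
  res <- glcm_grid_cpp(band, as.integer(window), as.integer(levels), offsets)
  names(res) <- c("ME", "VA", "HO", "CO", "DI", "EN", "SM", "CR")
  res
}

#' Co-occurrence matrix of a single window
#'
#' Exposes the quantization + accumulation step of [glcm_features()] for one
#' pixel neighbourhood: min-max quantize `values` to `levels`, accumulate the
#' symmetric co-occurrence counts over `offsets`, normalize to sum 1.
#'
#' @param values numeric matrix (one window).
#' @inheritParams glcm_features
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcm_matrix <- function(values, levels = 64, offsets = NULL, step = 1) {
  if (is.null(offsets))
    offsets <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  offsets <- matrix(as.integer(offsets * step), ncol = 2)
  glcm_window_cpp(values, as.integer(levels), offsets)
}

#' Haralick statistics of a normalized co-occurrence matrix
#'
#' @param P square matrix summing to 1.
#' @return named vector `ME, VA, HO, CO, DI, EN, SM, CR` (CR is `NA` for a
#'   degenerate single-entry matrix).
#' @export
glcm_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(rep(seq_len(L) - 1, L), L, L)
  j <- t(i)
  pi_ <- rowSums(P)
  mu <- sum((seq_len(L) - 1) * pi_)
  va <- sum(((seq_len(L) - 1) - mu)^2 * pi_)
  nz <- P > 0
  en <- -sum(P[nz] * log(P[nz]))
  cr <- if (va > 1e-15) sum((i - mu) * (j - mu) * P) / va else NA_real_
  c(ME = mu, VA = va,
    HO = sum(P / (1 + (i - j)^2)),
    CO = sum(P * (i - j)^2),
    DI = sum(P * abs(i - j)),
    EN = en,
    SM = sum(P^2),
    CR = cr)
}

#' Build the full regional covariate stack
#'
#' Derives the regional predictor set from a scene's raw grids: vegetation
#' indices, SAR transforms, GLCM textures of selected bands (naming
#' convention `<BAND>_<FEATURE>`, e.g. `B8_SM`), and terrain derivatives.
#'
#' @param scene a `regional_scene` (or any list with `grids` and
#'   `cell_size`).
#' @param texture_bands named character vector mapping output prefixes to
#'   band names, default `c(B3 = "green", B8 = "nir", B8A = "b8a")`.
#' @param glcm_window,glcm_levels texture parameters (defaults 5 and 64).
#' @return named list of covariate matrices.
#' @export
build_covariates <- function(scene,
                             texture_bands = c(B3 = "green", B8 = "nir", B8A = "b8a"),
                             glcm_window = 5, glcm_levels = 64) {
  g <- scene$grids
  out <- compute_indices(g)
  out <- c(out, sar_transforms(g$vv, g$vh))
  out$VV <- g$vv; out$VH <- g$vh
  for (pref in names(texture_bands)) {
    tx <- glcm_features(g[[texture_bands[[pref]]]],
                        window = glcm_window, levels = glcm_levels)
    names(tx) <- paste0(pref, "_", names(tx))
    out <- c(out, tx)
  }
  terr <- terrain_derivatives(g$dem, scene$cell_size)
  out$Slope <- terr$slope; out$Aspect <- terr$aspect
  out$Elevation <- terr$elevation
  out
}
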