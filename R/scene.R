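#' Configuration for a synthetic canopy-closure scene
#'
#' Bundles every tunable of the synthetic-scene generator. The defaults are
#' calibrated to the study conditions the package emulates: 54 field plots
#' whose canopy-closure marginal has min 0.20, max 0.83, mean 0.50 and SD
#' 0.176; LiDAR footprints strung along parallel orbital strips at 100 m
#' along-track spacing; and 44 uninformative distractor features next to the
#' six informative ones.
#'
#' @param grid_rows,grid_cols grid dimensions (cells); at least 32 each so
#'   5x5 texture windows are meaningful.
#' @param cell_size cell edge length in meters.
#' @param seed integer master seed; all generator randomness derives from it
#'   via [split_seed()].
#' @param coef_smoothness spatial wavelength (meters) of the spatially varying
#'   coefficient surfaces.
#' @param covariate_smoothness spatial wavelength (meters) of the band /
#'   backscatter / terrain fields; rougher than the coefficients so local
#'   regressions see covariate contrast.
#' @param fcc_noise_sd sd of the white noise added to the canopy-closure
#'   surface (proportion units).
#' @param plot_noise_sd sd of plot measurement noise (proportion units).
#' @param feature_noise multiplier on all footprint-feature noise sds; 0
#'   switches feature noise off entirely.
#' @param n_footprint_tracks number of parallel footprint strips.
#' @param along_track_spacing footprint spacing along a strip, meters.
#' @param track_azimuth strip azimuth in degrees clockwise from north
#'   (default 0 = north-south strips).
#' @param n_distractors number of uninformative footprint features.
#' @param plot_n number of field plots.
#' @param plot_beta_params shape parameters of the Beta law behind the plot
#'   marginal. The default `c(1.3741, 1.5606)` is calibrated so that the Beta
#'   *truncated to* `plot_bounds` has mean 0.50 and SD 0.176; see
#'   [beta_moment_match()] for the untruncated moment-matching helper.
#' @param plot_bounds truncation bounds of the plot marginal within \[0, 1\].
#' @param epsg EPSG code recorded on exported rasters.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 128, grid_cols = 128, cell_size = 30,
                         seed = 42L,
                         coef_smoothness = NULL,
                         covariate_smoothness = NULL,
                         fcc_noise_sd = 0.02,
                         plot_noise_sd = 0.03,
                         feature_noise = 1,
                         n_footprint_tracks = 27,
                         along_track_spacing = 100,
                         track_azimuth = 0,
                         n_distractors = 44,
                         plot_n = 54,
                         plot_beta_params = c(1.3741, 1.5606),
                         plot_bounds = c(0.20, 0.83),
                         epsg = 32647) {
  extent <- c(grid_cols, grid_rows) * cell_size
  if (is.null(coef_smoothness)) coef_smoothness <- min(extent) / 2
  if (is.null(covariate_smoothness)) covariate_smoothness <- min(extent) / 6
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              cell_size = cell_size, seed = as.integer(seed),
              coef_smoothness = coef_smoothness,
              covariate_smoothness = covariate_smoothness,
              fcc_noise_sd = fcc_noise_sd, plot_noise_sd = plot_noise_sd,
              feature_noise = feature_noise,
              n_footprint_tracks = as.integer(n_footprint_tracks),
              along_track_spacing = along_track_spacing,
              track_azimuth = track_azimuth,
              n_distractors = as.integer(n_distractors),
              plot_n = as.integer(plot_n),
              plot_beta_params = plot_beta_params,
              plot_bounds = plot_bounds, epsg = epsg)
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$grid_rows < 32 || cfg$grid_cols < 32)
    stop("grid must be at least 32x32 so 5x5 texture windows are usable")
  if (cfg$fcc_noise_sd < 0 || cfg$plot_noise_sd < 0 || cfg$feature_noise < 0)
    stop("noise sds must be nonnegative")
  if (cfg$n_footprint_tracks < 1) stop("need at least one footprint track")
  if (cfg$plot_n < 1) stop("plot_n must be positive")
  if (any(cfg$plot_beta_params <= 0)) stop("plot_beta_params must be positive")
  b <- cfg$plot_bounds
  if (length(b) != 2 || b[1] >= b[2] || b[1] < 0 || b[2] > 1)
    stop("plot_bounds must satisfy 0 <= lo < hi <= 1")
  invisible(cfg)
}

#' Moment-match a Beta distribution
#'
#' Solves the Beta shape parameters from a target mean and variance:
#' `alpha = mu * (mu (1 - mu) / var - 1)`, `beta = (1 - mu) * (...)`. With the
#' field-plot target (mean 0.50, variance 0.030976) this gives
#' alpha = beta = 3.535. Note this matches the *untruncated* Beta; the scene
#' generator's default `plot_beta_params` is instead calibrated on the Beta
#' truncated to the plot bounds, which requires smaller shapes.
#'
#' @param mean,variance target moments, with `variance < mean * (1 - mean)`.
#' @return named numeric vector `c(alpha, beta)`.
#' @export
beta_moment_match <- function(mean = 0.50, variance = 0.030976) {
  stopifnot(mean > 0, mean < 1, variance > 0, variance < mean * (1 - mean))
  k <- mean * (1 - mean) / variance - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Draw from the truncated-Beta plot marginal
#'
#' Inverse-CDF sampling of a Beta(`shape[1]`, `shape[2]`) truncated to
#' `bounds`. This is the marginal that plot measurements are rank-matched to.
#'
#' @param n number of draws.
#' @param shape Beta shape parameters.
#' @param bounds truncation interval within \[0, 1\].
#' @return numeric vector of length `n` inside `bounds`.
#' @export
draw_plot_marginal <- function(n, shape = c(1.3741, 1.5606),
                               bounds = c(0.20, 0.83)) {
  lo <- pbeta(bounds[1], shape[1], shape[2])
  hi <- pbeta(bounds[2], shape[1], shape[2])
  qbeta(runif(n, lo, hi), shape[1], shape[2])
}

#' Generate a synthetic regional scene
#'
#' Builds co-registered raster grids (visible/NIR reflectance, VV/VH
#' backscatter in dB, a DEM), a set of standardized regional covariates
#' derived from those grids, smooth spatially varying coefficient surfaces,
#' and the resulting true canopy-closure surface
#' `clamp01(a0(u,v) + sum_k a_k(u,v) z_k(u,v) + eps)`. Bands are driven by a
#' latent vegetation field so NDVI-type indices correlate positively with
#' canopy closure.
#'
#' @param config a [scene_config()].
#' @return a list of class `regional_scene`: `grids` (named matrices,
#'   including `true_fcc` and logical `mask`), `z` (standardized covariate
#'   grids used in the generating model), `coef` (true coefficient surfaces,
#'   intercept first), plus the lattice metadata.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  nr <- config$grid_rows; nc <- config$grid_cols; cs <- config$cell_size
  wl_cov <- config$covariate_smoothness / cs
  wl_coef <- config$coef_smoothness / cs

  fields <- with_stream_seed(config$seed, 1L, {
    V <- clamp01(0.5 + 0.22 * standardize_grid(
      0.7 * harmonic_field(nr, nc, wl_cov) + 0.3 * smooth_field(nr, nc, wl_cov)))
    M <- clamp01(0.5 + 0.22 * standardize_grid(
      0.7 * harmonic_field(nr, nc, wl_cov) + 0.3 * smooth_field(nr, nc, wl_cov)))
    # broad relief plus medium-scale ridges: local contrast keeps the
    # elevation coefficient identifiable in local regressions
    f_dem <- harmonic_field(nr, nc, 2 * wl_cov)
    f_relief <- smooth_field(nr, nc, wl_cov / 3)
    # pixel-scale texture: forest reflectance and speckle-filtered
    # backscatter retain strong fine-scale heterogeneity, which also keeps
    # local regression designs well conditioned
    nz <- function(s) s * smooth_field(nr, nc, 3)
    list(
      blue  = clamp_range(0.08 - 0.03 * V + nz(0.01), 0.005, 0.95),
      green = clamp_range(0.12 - 0.04 * V + nz(0.02), 0.005, 0.95),
      red   = clamp_range(0.30 - 0.22 * V + nz(0.045), 0.005, 0.95),
      nir   = clamp_range(0.20 + 0.45 * V + nz(0.06), 0.005, 0.95),
      vv    = -9  + 0.5 * V + 1.0 * M + nz(1.1),
      vh    = -17 + 1.0 * V + 4.0 * M + nz(1.4),
      dem   = 3400 + 350 * f_dem + 180 * f_relief
    )
  })
  fields$b8a <- clamp_range(0.95 * fields$nir + 0.01, 0.005, 0.95)

  ndvi <- (fields$nir - fields$red) / (fields$nir + fields$red)
  z <- list(
    ndvi = standardize_grid(ndvi),
    vv_minus_vh = standardize_grid(fields$vv - fields$vh),
    elevation = standardize_grid(fields$dem)
  )

  coef <- with_stream_seed(config$seed, 2L, {
    list(
      intercept   = 0.50 + 0.15 * harmonic_field(nr, nc, wl_coef),
      ndvi        = 0.12 + 0.10 * harmonic_field(nr, nc, wl_coef),
      vv_minus_vh = -0.06 + 0.06 * harmonic_field(nr, nc, wl_coef),
      elevation   = -0.05 + 0.055 * harmonic_field(nr, nc, wl_coef)
    )
  })

  lin <- coef$intercept
  for (k in names(z)) lin <- lin + coef[[k]] * z[[k]]
  eps <- if (config$fcc_noise_sd > 0) {
    with_stream_seed(config$seed, 3L,
                     matrix(rnorm(nr * nc, 0, config$fcc_noise_sd), nr, nc))
  } else matrix(0, nr, nc)
  true_fcc <- clamp01(lin + eps)

  grids <- c(fields, list(true_fcc = true_fcc))
  scene <- list(grids = grids, z = z, coef = coef,
                mask = matrix(TRUE, nr, nc),
                nrow = nr, ncol = nc, cell_size = cs,
                x0 = 0, y0 = 0, epsg = config$epsg, config = config)
  class(scene) <- "regional_scene"
  scene
}

## Footprint strip geometry: `n_footprint_tracks` parallel lines at the
## configured azimuth, evenly spaced across the scene with seeded jitter,
## sampled every `along_track_spacing` meters.
footprint_positions <- function(scene, config) {
  ext_x <- scene$ncol * scene$cell_size
  ext_y <- scene$nrow * scene$cell_size
  nt <- config$n_footprint_tracks
  az <- config$track_azimuth * pi / 180
  offs <- (seq_len(nt) - 0.5) / nt * ext_x
  offs <- offs + runif(nt, -0.25, 0.25) * ext_x / nt
  s <- seq(config$along_track_spacing / 2, ext_y - config$along_track_spacing / 2,
           by = config$along_track_spacing)
  x <- rep(offs, each = length(s)) + sin(az) * rep(s, nt)
  y <- cos(az) * rep(s, nt)
  keep <- x > 0 & x < ext_x & y > 0 & y < ext_y
  data.frame(x = x[keep], y = y[keep])
}

#' Derive footprint-scale LiDAR features over a scene
#'
#' Places footprints on parallel orbital strips and attaches six informative
#' segment features (monotone transforms of true canopy closure plus seeded
#' noise) and `n_distractors` uninformative features, half of them spatially
#' autocorrelated. The informative links are stand-ins for the unpublished
#' physical relations between segment statistics and canopy closure; their
#' slopes and noise scales are fixed package defaults.
#'
#' @param scene a [generate_scene()] result.
#' @param config the matching [scene_config()].
#' @return `data.frame` of class `footprint_table`: `id, x, y`, six named
#'   informative features (`landsat_perc`, `toc_roughness`, `h_min_canopy`,
#'   `h_dif_canopy`, `n_toc_photons`, `asr`), distractors `dist01...`, and
#'   `true_fcc`.
#' @export
make_footprint_features <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "regional_scene"))
  if (config$n_footprint_tracks < 1) stop("need at least one footprint track")
  with_stream_seed(config$seed, 4L, {
    pos <- footprint_positions(scene, config)
    n <- nrow(pos)
    fcc <- extract_at(scene$grids$true_fcc, scene$cell_size, pos$x, pos$y)
    s <- config$feature_noise
    nz <- function(sd) if (s > 0) rnorm(n, 0, sd * s) else 0
    # noise scales put small-sample model skill in the regime reported for
    # real segment features (LOOCV R2 roughly 0.2-0.65); photon counts are
    # overdispersed (Poisson with lognormal rate heterogeneity)
    lambda <- (10 + 60 * fcc) * if (s > 0) exp(rnorm(n, 0, 0.45 * s)) else 1
    n_toc <- if (s > 0) rpois(n, lambda) else round(lambda)
    tab <- data.frame(
      id = seq_len(n), x = pos$x, y = pos$y,
      landsat_perc = 100 * fcc + nz(12),
      toc_roughness = pmax(0.5 + 4.5 * fcc + nz(1.2), 0),
      h_min_canopy = pmax(1.5 + 2.0 * fcc + nz(1.0), 0),
      h_dif_canopy = pmax(0.5 + 5.0 * fcc + nz(1.8), 0),
      n_toc_photons = n_toc,
      asr = pmax(0.25 + 0.20 * fcc + nz(0.10), 0)
    )
    nd <- config$n_distractors
    if (nd > 0) {
      wl <- min(scene$nrow, scene$ncol) / 10
      for (k in seq_len(nd)) {
        val <- if (k %% 2 == 0) {
          g <- smooth_field(scene$nrow, scene$ncol, wl)
          extract_at(g, scene$cell_size, pos$x, pos$y)
        } else rnorm(n)
        tab[[sprintf("dist%02d", k)]] <- val
      }
    }
    tab$true_fcc <- fcc
    class(tab) <- c("footprint_table", "data.frame")
    tab
  })
}

#' Names of the informative footprint features
#' @return character vector of the six informative feature names.
#' @export
informative_features <- function() {
  c("landsat_perc", "toc_roughness", "h_min_canopy",
    "h_dif_canopy", "n_toc_photons", "asr")
}

feature_columns <- function(tab) {
  setdiff(names(tab), c("id", "x", "y", "true_fcc", "predicted_fcc"))
}

#' Sample field plots from a scene
#'
#' Draws `plot_n` plot locations at footprint positions, simulates measured
#' canopy closure as truth plus Gaussian measurement noise, then rank-matches
#' the noisy values to a truncated-Beta target sample so the plot marginal
#' reproduces the configured field statistics while preserving the spatial
#' association with the scene.
#'
#' @param scene a [generate_scene()] result.
#' @param config the matching [scene_config()].
#' @param footprints optional precomputed [make_footprint_features()] table;
#'   regenerated from `config` when omitted.
#' @param truncate logical; rank-match to the truncated Beta marginal
#'   (default) or return the raw noisy values.
#' @return `data.frame` of class `plot_sample` with `id, x, y, fcc_measured`
#'   and a `footprint_id` attribute-column linking each plot to its footprint.
#' @export
sample_plots <- function(scene, config = scene$config,
                         footprints = NULL, truncate = TRUE) {
  stopifnot(inherits(scene, "regional_scene"))
  if (is.null(footprints)) footprints <- make_footprint_features(scene, config)
  if (config$plot_n > nrow(footprints))
    stop("plot_n exceeds the number of available footprints")
  with_stream_seed(config$seed, 5L, {
    idx <- sample.int(nrow(footprints), config$plot_n)
    fcc <- footprints$true_fcc[idx]
    noisy <- fcc + if (config$plot_noise_sd > 0)
      rnorm(config$plot_n, 0, config$plot_noise_sd) else 0
    measured <- noisy
    if (truncate) {
      target <- sort(draw_plot_marginal(config$plot_n, config$plot_beta_params,
                                        config$plot_bounds))
      measured <- numeric(config$plot_n)
      measured[order(noisy)] <- target
    }
    out <- data.frame(id = seq_len(config$plot_n),
                      footprint_id = footprints$id[idx],
                      x = footprints$x[idx], y = footprints$y[idx],
                      fcc_measured = measured)
    class(out) <- c("plot_sample", "data.frame")
    out
  })
}

#' Write scene rasters, footprints, plots and config to a directory
#'
#' Rasters go to TIFF (+ JSON georeferencing sidecars), tables to CSV,
#' footprints optionally to GeoJSON, and the configuration to YAML.
#'
#' @param scene a `regional_scene`.
#' @param dir output directory (created if needed).
#' @param footprints,plots optional tables to write alongside.
#' @param geojson also write footprints as a GeoJSON point collection.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, footprints = NULL, plots = NULL,
                        geojson = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scene$grids)) {
    write_grid_tiff(scene$grids[[nm]], file.path(dir, paste0(nm, ".tif")),
                    scene$cell_size, scene$x0, scene$y0, scene$epsg)
  }
  yaml::write_yaml(unclass(scene$config), file.path(dir, "scene_config.yaml"))
  if (!is.null(footprints))
    write.csv(footprints, file.path(dir, "footprints.csv"), row.names = FALSE)
  if (!is.null(plots))
    write.csv(plots, file.path(dir, "plots.csv"), row.names = FALSE)
  if (geojson && !is.null(footprints)) {
    feats <- lapply(seq_len(nrow(footprints)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(footprints$x[i], footprints$y[i])),
           properties = as.list(footprints[i, setdiff(names(footprints),
                                                      c("x", "y"))]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         file.path(dir, "footprints.geojson"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
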