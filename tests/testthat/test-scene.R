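test_that("identical configs give bit-identical scenes, footprints and plots", {
  cfg <- scene_config(grid_rows = 48, grid_cols = 48, n_footprint_tracks = 8,
                      seed = 3L)
  a <- generate_scene(cfg); b <- generate_scene(cfg)
  expect_identical(a, b)
  fa <- make_footprint_features(a, cfg); fb <- make_footprint_features(b, cfg)
  expect_identical(fa, fb)
  pa <- sample_plots(a, cfg, footprints = fa)
  pb <- sample_plots(b, cfg, footprints = fb)
  expect_identical(pa, pb)
})

test_that("zero surface noise gives the clamped deterministic SVC surface", {
  cfg <- scene_config(grid_rows = 48, grid_cols = 48, fcc_noise_sd = 0, seed = 5L)
  sc <- generate_scene(cfg)
  lin <- sc$coef$intercept
  for (k in names(sc$z)) lin <- lin + sc$coef[[k]] * sc$z[[k]]
  expect_equal(sc$grids$true_fcc, clamp01(lin), tolerance = 1e-12)
})

test_that("canopy-closure grids are clamped and finite", {
  sc <- default_scene()$scene
  expect_true(all(sc$grids$true_fcc >= 0 & sc$grids$true_fcc <= 1))
  expect_false(anyNA(sc$grids$true_fcc))
})

test_that("grids below the texture-window minimum are rejected", {
  expect_error(scene_config(grid_rows = 16, grid_cols = 64), "32x32")
  expect_error(scene_config(fcc_noise_sd = -0.1), "nonnegative")
  expect_error(scene_config(plot_bounds = c(0.9, 0.2)), "plot_bounds")
})

test_that("zero feature noise makes landsat_perc exactly 100 x truth", {
  cfg <- scene_config(grid_rows = 48, grid_cols = 48, n_footprint_tracks = 8,
                      feature_noise = 0, seed = 9L)
  sc <- generate_scene(cfg)
  fp <- make_footprint_features(sc, cfg)
  expect_equal(fp$landsat_perc, 100 * fp$true_fcc, tolerance = 1e-12)
  expect_equal(fp$n_toc_photons, round(10 + 60 * fp$true_fcc))
})

test_that("footprint table carries exactly the six informative features plus distractors", {
  d <- default_scene()
  fp <- d$footprints
  expect_length(feature_columns(fp), 50)
  expect_true(all(informative_features() %in% names(fp)))
  expect_true(all(fp$n_toc_photons >= 0 & fp$n_toc_photons == round(fp$n_toc_photons)))
  ext <- c(d$cfg$grid_cols, d$cfg$grid_rows) * d$cfg$cell_size
  expect_true(all(fp$x > 0 & fp$x < ext[1] & fp$y > 0 & fp$y < ext[2]))
  expect_error(make_footprint_features(d$scene,
    utils::modifyList(d$cfg, list(n_footprint_tracks = 0L))), "track")
})

test_that("informative features dominate every distractor in correlation at n >= 5000", {
  cfg <- scene_config(n_footprint_tracks = 45, along_track_spacing = 25, seed = 7L)
  sc <- generate_scene(cfg)
  fp <- make_footprint_features(sc, cfg)
  expect_gte(nrow(fp), 5000)
  feats <- feature_columns(fp)
  r <- vapply(fp[feats], function(v) abs(cor(v, fp$true_fcc)), numeric(1))
  inf <- informative_features()
  expect_gt(min(r[inf]), max(r[setdiff(feats, inf)]))
})

test_that("plot samples respect count, bounds and footprint anchoring", {
  d <- default_scene()
  pl <- d$plots
  expect_equal(nrow(pl), 54L)
  expect_true(all(pl$fcc_measured >= 0.20 & pl$fcc_measured <= 0.83))
  expect_true(all(pl$footprint_id %in% d$footprints$id))
  expect_error(sample_plots(d$scene, utils::modifyList(d$cfg, list(plot_n = 10^6L)),
                            footprints = d$footprints), "exceeds")
})

test_that("rank-matching preserves the spatial association with the scene", {
  d <- default_scene()
  truth <- d$footprints$true_fcc[match(d$plots$footprint_id, d$footprints$id)]
  expect_gt(cor(d$plots$fcc_measured, truth), 0.8)
})

test_that("beta moment matching reproduces the closed-form shapes", {
  ab <- beta_moment_match(0.50, 0.030976)
  expect_equal(unname(ab[1]), 3.5354, tolerance = 1e-3)
  expect_equal(unname(ab[1]), unname(ab[2]))
  # round trip: moments of Beta(ab) are the requested ones
  a <- ab[1]; b <- ab[2]
  expect_equal(unname(a / (a + b)), 0.50, tolerance = 1e-12)
  expect_equal(unname(a * b / ((a + b)^2 * (a + b + 1))), 0.030976, tolerance = 1e-6)
})

test_that("default plot marginal reproduces the field mean and SD", {
  set.seed(123)
  draws <- draw_plot_marginal(10000)
  expect_true(all(draws >= 0.20 & draws <= 0.83))
  expect_lt(abs(mean(draws) - 0.50), 0.02)
  expect_lt(abs(sd(draws) - 0.176), 0.02)
})

test_that("scene writers round-trip grids and tables through disk", {
  d <- small_scene()
  out <- withr::local_tempdir()
  write_scene(d$scene, out, footprints = d$footprints[1:5, ], geojson = TRUE)
  expect_true(file.exists(file.path(out, "true_fcc.tif")))
  g <- read_grid_tiff(file.path(out, "true_fcc.tif"))
  expect_equal(dim(g), c(64, 64))
  expect_equal(unclass(g), unclass(d$scene$grids$true_fcc), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(g, "cell_size"), 30)
  gj <- jsonlite::read_json(file.path(out, "footprints.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 5)
  cfg2 <- yaml::read_yaml(file.path(out, "scene_config.yaml"))
  expect_equal(cfg2$seed, d$cfg$seed)
})
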