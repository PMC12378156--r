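mk <- function(v) matrix(v, 2, 2)

test_that("vegetation indices match their closed-form values", {
  b <- list(red = mk(0.1), nir = mk(0.5), green = mk(0.25), blue = mk(0.05))
  ix <- compute_indices(b)
  expect_equal(ix$NDVI[1, 1], (0.5 - 0.1) / 0.6, tolerance = 1e-12)
  expect_equal(ix$NDVI[1, 1], 0.6667, tolerance = 1e-3)
  expect_equal(ix$GNDVI[1, 1], (0.5 - 0.25) / 0.75, tolerance = 1e-12)
  expect_equal(ix$GNDVI[1, 1], 0.3333, tolerance = 1e-3)
  expect_equal(ix$DVI[1, 1], 0.4)
  expect_equal(ix$SAVI[1, 1], 1.5 * 0.4 / 1.1, tolerance = 1e-12)
  expect_equal(ix$EVI[1, 1], 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1), tolerance = 1e-12)
  # symmetry: NIR == Red gives zero
  ix0 <- compute_indices(list(red = mk(0.3), nir = mk(0.3), green = mk(0.2),
                              blue = mk(0.05)))
  expect_equal(ix0$NDVI[1, 1], 0)
  expect_true(all(abs(ix$NDVI) <= 1) && all(abs(ix$GNDVI) <= 1))
})

test_that("index computation flags missing bands and nodata denominators", {
  expect_error(compute_indices(list(nir = mk(0.5)), which = "NDVI"),
               "missing band 'red'")
  ix <- compute_indices(list(red = mk(0), nir = mk(0)), which = c("NDVI", "RVI"))
  expect_true(all(is.na(ix$NDVI)))
  expect_true(all(is.na(ix$RVI)))
})

test_that("SAR transforms follow the dB and linear-power conventions", {
  eq <- sar_transforms(mk(-10), mk(-10))
  expect_equal(eq$VV_minus_VH[1, 1], 0)
  expect_equal(eq$VV_over_VH[1, 1], 1)
  tr <- sar_transforms(mk(-8), mk(-14))
  expect_equal(tr$VV_minus_VH[1, 1], 6)
  expect_equal(tr$VV_over_VH[1, 1], 10^0.6, tolerance = 1e-12)
  expect_equal(tr$VV_over_VH[1, 1], 3.981, tolerance = 1e-3)
  expect_error(sar_transforms(mk(-8), matrix(-14, 3, 3)), "shape")
})

test_that("GLCM of a constant image hits the closed-form extremes", {
  g <- glcm_features(matrix(7.7, 12, 12), window = 5, levels = 64)
  expect_equal(g$CO[6, 6], 0); expect_equal(g$DI[6, 6], 0)
  expect_equal(g$EN[6, 6], 0); expect_equal(g$SM[6, 6], 1)
  expect_equal(g$HO[6, 6], 1); expect_true(is.na(g$CR[6, 6]))
})

test_that("hand-built checkerboard co-occurrence matches theory", {
  P <- glcm_matrix(matrix(c(0, 1, 1, 0), 2, 2), levels = 2,
                   offsets = rbind(c(0L, 1L)))
  expect_equal(P[1, 2], 0.5); expect_equal(P[2, 1], 0.5)
  expect_equal(sum(P), 1)
  st <- glcm_stats(P)
  expect_equal(unname(st["CO"]), 1)
  expect_equal(unname(st["SM"]), 0.5)
  expect_equal(unname(st["EN"]), log(2), tolerance = 1e-12)
})

test_that("compiled GLCM agrees with the brute-force R implementation", {
  set.seed(42)
  band <- matrix(runif(100), 10, 10)
  offs <- rbind(c(0L, 1L), c(1L, 0L))
  fast <- glcm_features(band, window = 3, levels = 8, offsets = offs)
  slow <- brute_glcm(band, window = 3, levels = 8, offsets = offs)
  for (k in names(fast))
    expect_equal(fast[[k]], slow[[k]], tolerance = 1e-10, ignore_attr = TRUE)
  # exposed intermediate: normalized matrix sums to one
  P <- glcm_matrix(band[1:5, 1:5], levels = 8)
  expect_equal(sum(P), 1, tolerance = 1e-12)
  Pb <- brute_cooc(band[1:5, 1:5], 8, rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)))
  expect_equal(P, Pb, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GLCM rejects invalid windows and tiny grids", {
  expect_error(glcm_features(matrix(0, 10, 10), window = 4), "odd")
  expect_error(glcm_features(matrix(0, 3, 3), window = 5), "too small")
  expect_error(glcm_features(matrix(0, 10, 10), levels = 1), "levels")
})

test_that("terrain derivatives recover an analytic plane", {
  dem <- outer(rep(1, 10), seq_len(10)) * 0.1  # z = 0.1 * x, 1 m cells
  td <- terrain_derivatives(dem, cell_size = 1)
  expect_equal(td$slope[5, 5], atan(0.1) * 180 / pi, tolerance = 1e-10)
  expect_equal(td$slope[5, 5], 5.71, tolerance = 1e-2)
  expect_equal(td$aspect[5, 5], 270)  # downhill toward -x (west)
  expect_identical(td$elevation, dem)
  # slope invariant to a vertical shift
  td2 <- terrain_derivatives(dem + 100, cell_size = 1)
  expect_equal(td2$slope, td$slope, tolerance = 1e-12)
  # x<->y transposition rotates the aspect of a plane by 90 degrees
  td3 <- terrain_derivatives(t(dem), cell_size = 1)
  expect_equal((td$aspect[5, 5] - td3$aspect[5, 5]) %% 360, 90)
})

test_that("flat terrain gets zero slope and the aspect sentinel", {
  td <- terrain_derivatives(matrix(500, 6, 6), cell_size = 30)
  expect_true(all(td$slope == 0))
  expect_true(all(td$aspect == -1))
  expect_error(terrain_derivatives(matrix(0, 2, 2), 1), "3x3")
  expect_error(terrain_derivatives(matrix(0, 6, 6), 0), "cell_size")
})

test_that("the covariate stack follows the naming convention and bounds", {
  sc <- small_scene()$scene
  cov <- build_covariates(sc, texture_bands = c(B8 = "nir"))
  expect_true(all(c("NDVI", "GNDVI", "VV_minus_VH", "VV_over_VH",
                    "B8_ME", "B8_EN", "B8_SM", "B8_CR",
                    "Slope", "Aspect", "Elevation") %in% names(cov)))
  expect_true(all(dim(cov$NDVI) == c(64, 64)))
  expect_true(all(abs(cov$NDVI) <= 1, na.rm = TRUE))
  expect_true(all(cov$B8_SM > 0 & cov$B8_SM <= 1, na.rm = TRUE))
  expect_true(all(cov$B8_HO > 0 & cov$B8_HO <= 1, na.rm = TRUE))
  expect_true(all(cov$B8_CO >= 0, na.rm = TRUE))
  expect_true(all(cov$B8_EN >= 0, na.rm = TRUE))
  expect_true(all(cov$Slope >= 0 & cov$Slope < 90))
})
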