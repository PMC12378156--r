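toy_gwr <- function(n = 30, seed = 17, p = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  beta0 <- 0.3 + coords[, 1] / 2000
  y <- beta0 + 0.2 * X[, 1] - 0.1 * X[, 2] + rnorm(n, 0, 0.05)
  list(X = X, y = y, coords = coords)
}

test_that("kernel weights match their closed forms", {
  expect_equal(kernel_weights(0, 5, "gaussian"), 1)
  expect_equal(kernel_weights(0, 5, "bisquare"), 1)
  expect_equal(kernel_weights(5, 5, "gaussian"), exp(-1))
  expect_equal(kernel_weights(5, 5, "gaussian"), 0.367879, tolerance = 1e-5)
  expect_equal(kernel_weights(2.5, 5, "bisquare"), 0.5625)
  expect_equal(kernel_weights(c(5, 7), 5, "bisquare"), c(0, 0))
  w <- kernel_weights(seq(0, 10, 0.5), 3, "gaussian")
  expect_true(all(w >= 0 & w <= 1))
  expect_error(kernel_weights(1, 0, "gaussian"), "positive")
})

test_that("AICc follows the adopted hat-trace form", {
  expect_equal(aicc_score(1.0, 100, 10), -151.73, tolerance = 1e-2)
  expect_gt(aicc_score(2.0, 100, 10), aicc_score(1.0, 100, 10))
  expect_error(aicc_score(1.0, 100, 98), "infeasible")
})

test_that("local coefficients match brute-force weighted normal equations", {
  d <- toy_gwr(n = 50)
  cfg <- gwr_config(kernel = "gaussian", bandwidth_mode = "fixed_distance",
                    bandwidth = 300)
  fit <- fit_gwr(d$X, d$y, d$coords, cfg)
  Xd <- cbind(1, d$X)
  for (i in c(1, 13, 50)) {
    dist_i <- sqrt(colSums((t(d$coords) - d$coords[i, ])^2))
    w <- exp(-dist_i^2 / 300^2)
    expect_equal(unname(fit$coef[i, ]), as.numeric(brute_wls(Xd, d$y, w)),
                 tolerance = 1e-8)
  }
  expect_equal(fit$residuals, d$y - fit$fitted, tolerance = 1e-12)
})

test_that("an infinite Gaussian bandwidth collapses GWR to global least squares", {
  d <- toy_gwr(n = 6, seed = 2)
  cfg <- gwr_config(kernel = "gaussian", bandwidth_mode = "fixed_distance",
                    bandwidth = 1e9)
  fit <- fit_gwr(d$X, d$y, d$coords, cfg)
  ols <- unname(coef(lm(d$y ~ d$X)))
  for (i in seq_len(6))
    expect_lt(max(abs(fit$coef[i, ] - ols)), 1e-6)
  expect_equal(fit$trace_S, ncol(d$X) + 1, tolerance = 1e-6)
  expect_equal(fit$fitted, unname(fitted(lm(d$y ~ d$X))), tolerance = 1e-6)
})

test_that("fits carry the dimensional contracts and translation invariance", {
  d <- toy_gwr(n = 40)
  cfg <- gwr_config(bandwidth = 20)  # adaptive bisquare, 20 neighbors
  fit <- fit_gwr(d$X, d$y, d$coords, cfg)
  expect_equal(dim(fit$coef), c(40, 3))
  expect_gte(fit$trace_S, 3); expect_lte(fit$trace_S, 40)
  fit2 <- fit_gwr(d$X, d$y, d$coords + 1000, cfg)
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-9)
  expect_equal(fit2$fitted, fit$fitted, tolerance = 1e-9)
})

test_that("lon/lat-looking coordinates are rejected", {
  d <- toy_gwr(n = 20)
  ll <- cbind(runif(20, 99.4, 99.5), runif(20, 27.1, 27.2))
  expect_error(fit_gwr(d$X, d$y, ll, gwr_config(bandwidth = 10)), "geographic")
})

test_that("singular local systems use the ridge fallback or error at zero", {
  d <- toy_gwr(n = 25)
  X <- cbind(d$X, dup = d$X[, 1])
  cfg <- gwr_config(kernel = "gaussian", bandwidth_mode = "fixed_distance",
                    bandwidth = 500)
  expect_warning(fit <- fit_gwr(X, d$y, d$coords, cfg), "ridge")
  expect_true(all(is.finite(fit$fitted)))
  cfg0 <- cfg; cfg0$ridge_fallback <- 0
  expect_error(suppressWarnings(fit_gwr(X, d$y, d$coords, cfg0)), "singular")
})

test_that("golden-section bandwidth selection tracks a dense-grid oracle", {
  d <- small_scene()
  sd_ <- scene_design(d$scene, d$footprints)
  sub <- seq_len(120)
  X <- sd_$X[sub, ]; y <- sd_$y[sub]; coords <- sd_$coords[sub, ]
  cfg <- gwr_config()
  sel <- select_bandwidth(X, y, coords, cfg)
  # dense integer grid over the same bounds
  ks <- (ncol(X) + 2):120
  aiccs <- vapply(ks, function(k) {
    g <- cfg; g$bandwidth <- k
    fit <- tryCatch(fit_gwr(X, y, coords, g), error = function(e) NULL)
    if (is.null(fit) || is.na(fit$aicc)) Inf else fit$aicc
  }, numeric(1))
  best_dense <- min(aiccs)
  expect_lte(sel$aicc, best_dense + 0.005 * abs(best_dense))
  # profile endpoints never undercut the returned minimum
  expect_true(all(sel$profile$aicc[is.finite(sel$profile$aicc)] >= sel$aicc))
})

test_that("predictions refit the local system and respect the contracts", {
  d <- toy_gwr(n = 40)
  cfg <- gwr_config(bandwidth = 25)
  fit <- fit_gwr(d$X, d$y, d$coords, cfg)
  # at a training location with its own covariate row: the in-sample fit
  pr <- predict_gwr(fit, d$coords[7, , drop = FALSE], d$X[7, , drop = FALSE],
                    clamp = FALSE)
  expect_equal(pr$pred, fit$fitted[7], tolerance = 1e-10)
  # translation invariance
  fit2 <- fit_gwr(d$X, d$y, d$coords + 500, cfg)
  pr2 <- predict_gwr(fit2, d$coords[7, , drop = FALSE] + 500,
                     d$X[7, , drop = FALSE], clamp = FALSE)
  expect_equal(pr2$pred, pr$pred, tolerance = 1e-9)
  expect_error(predict_gwr(fit, d$coords[1:3, ], d$X[1:3, 1, drop = FALSE]),
               "columns")
})

test_that("an infinite bandwidth makes predictions global least squares", {
  d <- toy_gwr(n = 30, seed = 5)
  cfg <- gwr_config(kernel = "gaussian", bandwidth_mode = "fixed_distance",
                    bandwidth = 1e9)
  fit <- fit_gwr(d$X, d$y, d$coords, cfg)
  new_coords <- cbind(runif(5, 0, 1000), runif(5, 0, 1000))
  new_X <- matrix(rnorm(10), 5, 2)
  pr <- predict_gwr(fit, new_coords, new_X, clamp = FALSE)
  lmfit <- lm(d$y ~ d$X)
  expected <- cbind(1, new_X) %*% coef(lmfit)
  expect_equal(pr$pred, as.numeric(expected), tolerance = 1e-6)
})

test_that("bisquare prediction beyond every kernel support returns nodata", {
  d <- toy_gwr(n = 20)
  cfg <- gwr_config(kernel = "bisquare", bandwidth_mode = "fixed_distance",
                    bandwidth = 50)
  fit <- fit_gwr(d$X, d$y, d$coords, cfg)
  far <- matrix(c(1e6, 1e6), 1, 2)
  expect_warning(pr <- predict_gwr(fit, far, d$X[1, , drop = FALSE]), "zero kernel")
  expect_true(is.na(pr$pred))
})

test_that("local coefficient surfaces are recovered on the synthetic SVC scene", {
  d <- default_scene()
  sd_ <- scene_design(d$scene, d$footprints)
  cfg <- gwr_config()
  sel <- select_bandwidth(sd_$X, sd_$y, sd_$coords, cfg)
  g <- cfg; g$bandwidth <- sel$bandwidth
  fit <- fit_gwr(sd_$X, sd_$y, sd_$coords, g)
  truth <- lapply(d$scene$coef, extract_at, cell_size = d$scene$cell_size,
                  x = d$footprints$x, y = d$footprints$y)
  for (k in seq_along(truth))
    expect_gte(cor(truth[[k]], fit$coef[, k]), 0.9)
  # summary diagnostics are well-formed
  s <- gwr_summary(fit)
  expect_true(s$trace_S > ncol(sd_$X) + 1 && s$trace_S < length(sd_$y))
  expect_true(is.finite(s$aicc))
})
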