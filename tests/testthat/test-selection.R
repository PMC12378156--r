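test_that("random-forest importance ranks planted signals on top", {
  set.seed(1)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  noise <- as.data.frame(matrix(rnorm(n * 8), n))
  names(noise) <- paste0("n", 1:8)
  y <- x1 + 0.5 * x2 + rnorm(n, 0, 0.3)
  rep <- rf_importance_select(cbind(data.frame(x1 = x1, x2 = x2), noise), y,
                              seed = 99L)
  expect_equal(rep$name[1:2], c("x1", "x2"))
  expect_equal(sum(rep$importance_share), 1, tolerance = 1e-12)
  expect_setequal(kept_variables(rep),
                  rep$name[rep$importance_share >= 0.05])
})

test_that("exchangeable variables share importance and all pass at 5%", {
  set.seed(2)
  n <- 400
  X <- as.data.frame(matrix(rnorm(n * 10), n))
  y <- rowSums(X) + rnorm(n, 0, 0.5)
  rep <- rf_importance_select(X, y, threshold = 0.05, seed = 4L)
  expect_true(all(rep$decision == "kept"))
  expect_true(all(abs(rep$importance_share - 0.1) < 0.05))
})

test_that("importance screen rejects degenerate inputs", {
  X <- data.frame(a = rnorm(30), b = rep(NA_real_, 30))
  expect_error(rf_importance_select(X, rnorm(30)), "all-NaN.*b")
  expect_error(rf_importance_select(data.frame(a = rnorm(30)), rep(1, 30)),
               "constant")
  expect_error(rf_importance_select(data.frame(a = rnorm(5)), rnorm(5)), "10")
})

test_that("Pearson screen keeps strong correlates and drops noise", {
  set.seed(3)
  y <- rnorm(1000)
  X <- data.frame(same = y,
                  weak = 0.22 * y + rnorm(1000) * sqrt(1 - 0.22^2),
                  indep = rnorm(1000),
                  flat = rep(1, 1000))
  rep <- pearson_screen(X, y)
  expect_equal(rep$decision[rep$name == "same"], "kept")
  expect_equal(rep$pearson_r[rep$name == "same"], 1)
  expect_equal(rep$decision[rep$name == "indep"], "dropped")
  expect_equal(rep$decision[rep$name == "flat"], "dropped")
  expect_match(rep$reason[rep$name == "flat"], "zero variance")
})

test_that("a correlation at the 0.220 boundary magnitude survives the screen", {
  # construct a variable with |r| exactly 0.220 against the target
  set.seed(8)
  n <- 5000
  y <- rnorm(n)
  e <- rnorm(n); e <- residuals(lm(e ~ y))  # exactly orthogonal to y
  x <- 0.220 * scale(y)[, 1] + sqrt(1 - 0.220^2) * scale(e)[, 1]
  r_emp <- cor(x, y)
  expect_equal(abs(r_emp), 0.220, tolerance = 1e-3)
  rep <- pearson_screen(data.frame(gndvi_like = x), y, r_min = 0.2, alpha = 0.01)
  expect_equal(rep$decision, "kept")
})

test_that("Pearson screen is invariant to affine rescaling", {
  set.seed(4)
  y <- rnorm(200)
  x <- 0.5 * y + rnorm(200)
  a <- pearson_screen(data.frame(x = x), y)
  b <- pearson_screen(data.frame(x = -3 + 40 * x), y)
  expect_equal(abs(a$pearson_r), abs(b$pearson_r), tolerance = 1e-12)
  expect_equal(a$decision, b$decision)
})

test_that("VIF filter removes exact duplicates without crashing", {
  set.seed(5)
  x <- rnorm(100)
  X <- data.frame(a = x, b = x, c = rnorm(100))
  rep <- vif_filter(X)
  expect_equal(sum(rep$decision == "dropped"), 1)
  expect_true(all(rep$vif[rep$decision == "kept"] <= 10))
})

test_that("orthogonal centered predictors all have VIF 1 and are kept", {
  set.seed(12)
  Q <- qr.Q(qr(matrix(rnorm(200 * 4), 200)))
  X <- as.data.frame(scale(Q, center = TRUE, scale = FALSE))
  rep <- vif_filter(X)
  expect_true(all(rep$decision == "kept"))
  expect_equal(rep$vif, rep(1, 4), tolerance = 1e-3)
})

test_that("a moderately collinear retained set passes wholesale at VIF 10", {
  # two predictors sharing a common factor (VIF ~ 6-7), four near-independent
  set.seed(6)
  n <- 2000
  f <- rnorm(n)
  X <- data.frame(v1 = f + 0.42 * rnorm(n), v2 = f + 0.42 * rnorm(n),
                  v3 = rnorm(n), v4 = rnorm(n), v5 = rnorm(n), v6 = rnorm(n))
  rep <- vif_filter(X, max_vif = 10)
  expect_true(all(rep$decision == "kept"))
  expect_true(all(rep$vif[rep$name %in% c("v1", "v2")] > 2))
  expect_true(max(rep$vif) <= 10)
})

test_that("iterative removal always lands below the threshold", {
  set.seed(7)
  n <- 300
  f <- rnorm(n)
  X <- data.frame(a = f + 0.1 * rnorm(n), b = f + 0.1 * rnorm(n),
                  c = f + 0.1 * rnorm(n), d = rnorm(n))
  rep <- vif_filter(X, max_vif = 10)
  kept <- kept_variables(rep)
  expect_gt(length(kept), 0)
  expect_true(all(rep$vif[rep$decision == "kept"] <= 10))
  # deterministic worst-first rule
  rep2 <- vif_filter(X, max_vif = 10)
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
})

test_that("omnibus normality test calibrates on normal and flags skewed data", {
  set.seed(9)
  x <- rnorm(5000)
  t1 <- dagostino_test(x)
  expect_gt(t1$p_value, 0.05)
  t2 <- dagostino_test(rexp(5000))
  expect_lt(t2$p_value, 1e-6)
  expect_error(dagostino_test(rep(3, 100)), "constant")
  expect_error(dagostino_test(rnorm(10)), "n >= 20")
})

test_that("normality assessment applies a power transform where needed", {
  set.seed(10)
  X <- data.frame(gauss = rnorm(5000), lnorm = rlnorm(5000, 0, 0.6))
  out <- withr::local_tempdir()
  rep <- normality_assess(X, hist_dir = out)
  expect_true(rep$normal[rep$name == "gauss"])
  expect_equal(rep$applied_transform[rep$name == "gauss"], "none")
  expect_equal(rep$applied_transform[rep$name == "lnorm"], "power")
  expect_true(rep$normal[rep$name == "lnorm"])
  expect_lt(abs(rep$lambda[rep$name == "lnorm"]), 0.2)
  expect_lt(rep$raw_p_value[rep$name == "lnorm"], 0.05)
  expect_true(file.exists(file.path(out, "lnorm.png")))
  expect_error(normality_assess(data.frame(k = rep(1, 100))), "constant")
})

test_that("selection reports serialize to CSV and JSON", {
  set.seed(11)
  rep <- pearson_screen(data.frame(x = rnorm(50)), rnorm(50))
  base <- file.path(withr::local_tempdir(), "screen")
  write_selection_report(rep, base)
  expect_true(file.exists(paste0(base, ".csv")))
  j <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(j$method, "pearson_screen")
})
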