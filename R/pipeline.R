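#' Relative-improvement percentages between model metrics
#'
#' Computes `100 * (after - before) / denominator`, sign-adjusted so that
#' improvements are positive: for `metric_type = "gain"` (R-squared, P) an
#' increase is positive, for `"error"` (RMSE, MAR, AICc) a decrease is
#' positive. The denominator convention is explicit — `"delta_over_before"`
#' divides by the pre-optimization value, `"delta_over_after"` by the
#' post-optimization value — and is recorded in the result, because
#' comparison tables in the literature mix both. Vector inputs give the
#' per-pair changes and their average.
#'
#' @param before,after numeric vectors of matching metrics.
#' @param convention denominator convention.
#' @param metric_type `"gain"` or `"error"`.
#' @return list with `percent` (mean change), `per_pair`, `convention`,
#'   `metric_type`. A zero denominator flags `NA` with a warning.
#' @export
report_improvements <- function(before, after,
                                convention = c("delta_over_before", "delta_over_after"),
                                metric_type = c("gain", "error")) {
  convention <- match.arg(convention)
  metric_type <- match.arg(metric_type)
  stopifnot(length(before) == length(after))
  delta <- if (metric_type == "gain") after - before else before - after
  den <- if (convention == "delta_over_before") before else after
  if (any(den == 0)) {
    warning("zero baseline; improvement undefined")
    den[den == 0] <- NA_real_
  }
  per <- 100 * delta / abs(den)
  list(percent = mean(per), per_pair = per,
       convention = if (length(per) > 1) paste0("averaged_", convention) else convention,
       metric_type = metric_type)
}

#' Canopy-closure class proportions of a map
#'
#' Shares of valid cells per class, default classes \[0, 0.3), \[0.3, 0.6),
#' \[0.6, 1\] (half-open, last closed). `NA` cells are excluded from the
#' denominator.
#'
#' @param map numeric matrix/vector of canopy-closure values in \[0, 1\] or `NA`.
#' @param bins increasing break points, default `c(0, 0.3, 0.6, 1)`.
#' @return named numeric vector of proportions summing to 1.
#' @export
fcc_distribution <- function(map, bins = c(0, 0.3, 0.6, 1)) {
  v <- as.vector(map)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no valid cells")
  k <- findInterval(v, bins, rightmost.closed = TRUE, all.inside = FALSE)
  k[k == 0] <- 1; k[k == length(bins)] <- length(bins) - 1
  counts <- tabulate(k, nbins = length(bins) - 1)
  props <- counts / sum(counts)
  names(props) <- paste0("[", head(bins, -1), ",", bins[-1],
                         c(rep(")", length(bins) - 2), "]"))
  props
}

#' Validate a canopy-closure map against field plots
#'
#' Looks up the predicted value at each plot location (nearest cell) and
#' scores agreement with the plot measurements: R-squared by the package's
#' sum-of-squares-about-the-observed-mean formula and the Pearson
#' correlation with its two-sided p-value. Plots falling on nodata or
#' outside the raster are excluded and counted.
#'
#' @param map numeric matrix (canopy-closure map).
#' @param plots a `plot_sample` with `x`, `y`, `fcc_measured`.
#' @param cell_size,x0,y0 the map's lattice geometry.
#' @return list with `r2`, `pearson_r`, `p_value`, `n`, `n_excluded`.
#' @export
validate_against_plots <- function(map, plots, cell_size, x0 = 0, y0 = 0) {
  pred <- extract_at(map, cell_size, plots$x, plots$y, x0, y0)
  ok <- !is.na(pred)
  if (sum(ok) < 3) stop("fewer than 3 co-located plot/prediction pairs")
  m <- eval_metrics(plots$fcc_measured[ok], pred[ok])
  ct <- cor.test(pred[ok], plots$fcc_measured[ok])
  list(r2 = m$r2, rmse = m$rmse, pearson_r = unname(ct$estimate),
       p_value = ct$p.value, n = sum(ok), n_excluded = sum(!ok))
}

## polynomial rolling hash over the serialized object; fingerprints a config
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, xdr = TRUE))
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param scene a [scene_config()] (synthetic mode).
#' @param models learner types to tune at the footprint stage.
#' @param budget,n_init BO budget per learner (total / initial evaluations).
#' @param seed master seed; overrides `scene$seed`.
#' @param importance_threshold footprint-stage importance-share gate.
#' @param r_min,alpha_r Pearson screen parameters (regional stage).
#' @param max_vif VIF filter threshold.
#' @param alpha_norm normality-test level.
#' @param gwr a [gwr_config()]; adaptive bisquare by default.
#' @param map_stride predict the map on every `map_stride`-th cell.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), models = c("knn", "rfr", "gbrt"),
                            budget = 50, n_init = 10, seed = scene$seed,
                            importance_threshold = 0.05,
                            r_min = 0.2, alpha_r = 0.01, max_vif = 10,
                            alpha_norm = 0.05,
                            gwr = gwr_config(), map_stride = 1) {
  scene$seed <- as.integer(seed)
  structure(list(scene = scene, models = models, budget = budget,
                 n_init = n_init, seed = as.integer(seed),
                 importance_threshold = importance_threshold,
                 r_min = r_min, alpha_r = alpha_r, max_vif = max_vif,
                 alpha_norm = alpha_norm, gwr = gwr,
                 map_stride = as.integer(map_stride)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the two-stage canopy-closure pipeline end to end
#'
#' Synthetic mode: generates the scene, footprints and plots; screens
#' footprint features by random-forest importance; tunes and selects the
#' footprint learner; predicts canopy closure for every footprint (with both
#' tuned and default-parameter labels); derives the regional covariate
#' stack; screens it (Pearson, VIF, normality with optional power
#' transforms); selects the GWR bandwidth by AICc and fits GWR on the tuned
#' footprint labels (and on the default labels for comparison); predicts the
#' wall-to-wall map; and reports class proportions, plot validation,
#' improvement percentages and map-vs-truth accuracy. Fully reproducible
#' from the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts (map TIFF, tables CSV,
#'   report JSON).
#' @param quiet suppress stage messages.
#' @return a `pipeline_report` list; see the elements of the returned object.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  say("scene: generating %dx%d grid (seed %d)",
      config$scene$grid_rows, config$scene$grid_cols, config$seed)
  scene <- stage("scene", generate_scene(config$scene))
  fp <- stage("footprints", make_footprint_features(scene, config$scene))
  plots <- stage("plots", sample_plots(scene, config$scene, footprints = fp))

  say("footprint stage: %d footprints, %d plots", nrow(fp), nrow(plots))
  train_idx <- match(plots$footprint_id, fp$id)
  feats <- fp[train_idx, feature_columns(fp), drop = FALSE]
  target <- plots$fcc_measured
  imp <- stage("importance", rf_importance_select(
    feats, target, threshold = config$importance_threshold,
    seed = split_seed(config$seed, 21L)))
  kept_fp <- kept_variables(imp)
  if (length(kept_fp) == 0) stop("[stage importance] no feature passed the gate")
  say("importance gate kept %d features: %s", length(kept_fp),
      paste(kept_fp, collapse = ", "))

  ms <- stage("tuning", train_and_select(
    feats[kept_fp], target, models = config$models,
    budget = config$budget, n_init = config$n_init,
    seed = split_seed(config$seed, 22L)))
  say("selected %s (LOOCV R2 %.3f)", ms$best_type, ms$reports[[ms$best_type]]$r2)

  fit_seed <- split_seed(config$seed, 23L)
  best_fit <- fit_learner(ms$best, feats[kept_fp], target, seed = fit_seed)
  base_fit <- fit_learner(list(type = ms$best_type,
                               params = default_params(ms$best_type)),
                          feats[kept_fp], target, seed = fit_seed)
  fp <- stage("footprint_predict", predict_footprints(best_fit, fp))
  labels_opt <- fp$predicted_fcc
  labels_base <- clamp01(predict_learner(base_fit, fp))

  say("regional stage: deriving covariates")
  cov <- stage("covariates", build_covariates(scene))
  cov_fp <- as.data.frame(lapply(cov, extract_at, cell_size = scene$cell_size,
                                 x = fp$x, y = fp$y))
  usable <- vapply(cov_fp, function(x) all(is.finite(x)), logical(1))
  cov_fp <- cov_fp[usable]
  ps <- stage("pearson", pearson_screen(cov_fp, labels_opt,
                                        r_min = config$r_min, alpha = config$alpha_r))
  kept1 <- kept_variables(ps)
  if (length(kept1) < 2) stop("[stage pearson] fewer than 2 covariates passed")
  vf <- stage("vif", vif_filter(cov_fp[kept1], max_vif = config$max_vif))
  kept2 <- kept_variables(vf)
  na <- stage("normality", normality_assess(cov_fp[kept2],
                                            alpha = config$alpha_norm))
  kept3 <- kept_variables(na)
  if (length(kept3) == 0) kept3 <- kept2  # keep the design; record the failures
  say("regional screens kept %d covariates: %s", length(kept3),
      paste(kept3, collapse = ", "))
  lambdas <- setNames(na$lambda[match(kept3, na$name)], kept3)
  families <- setNames(na$transform_family[match(kept3, na$name)], kept3)

  design_col <- function(values, nm) {
    lam <- lambdas[[nm]]
    if (is.null(lam) || !is.finite(lam)) return(values)
    if (identical(families[[nm]], "bcPower")) {
      out <- rep(NA_real_, length(values))  # Box-Cox needs positive input
      pos <- is.finite(values) & values > 0
      out[pos] <- car::bcPower(values[pos], lam)
      out
    } else car::yjPower(values, lam)
  }
  Xfp <- as.data.frame(lapply(kept3, function(nm) design_col(cov_fp[[nm]], nm)))
  names(Xfp) <- kept3
  # standardize the design: covariates arrive on wildly different scales
  # (dB, degrees, power-transformed meters) and local systems must stay
  # well conditioned; coefficients are reported on the standardized scale
  design_center <- vapply(Xfp, mean, numeric(1))
  design_scale <- vapply(Xfp, stats::sd, numeric(1))
  design_scale[design_scale == 0] <- 1
  Xfp <- as.data.frame(scale(Xfp, design_center, design_scale))
  coords <- cbind(fp$x, fp$y)

  say("GWR: selecting bandwidth (%s, %s)", config$gwr$kernel,
      config$gwr$bandwidth_mode)
  gsearch <- config$gwr
  if (is.null(gsearch$search_bounds) &&
      gsearch$bandwidth_mode == "adaptive_neighbors") {
    # at least twice the local parameter count, so every local system stays
    # overdetermined under the compact-support kernel
    gsearch$search_bounds <- c(2 * (ncol(Xfp) + 1), nrow(Xfp))
  }
  sel <- stage("bandwidth", select_bandwidth(Xfp, labels_opt, coords, gsearch))
  gcfg <- config$gwr; gcfg$bandwidth <- sel$bandwidth
  gm_opt <- stage("gwr_fit", fit_gwr(Xfp, labels_opt, coords, gcfg))
  sel_base <- stage("bandwidth_base",
                    select_bandwidth(Xfp, labels_base, coords, gsearch))
  gcfg_base <- config$gwr; gcfg_base$bandwidth <- sel_base$bandwidth
  gm_base <- stage("gwr_fit_base", fit_gwr(Xfp, labels_base, coords, gcfg_base))

  say("GWR: predicting the map (stride %d)", config$map_stride)
  st <- config$map_stride
  ri <- seq(1, scene$nrow, by = st); ci <- seq(1, scene$ncol, by = st)
  xy <- grid_xy(scene$nrow, scene$ncol, scene$cell_size, scene$x0, scene$y0)
  cells <- expand.grid(i = ri, j = ci)
  newX <- as.data.frame(lapply(kept3, function(nm)
    design_col(cov[[nm]][cbind(cells$i, cells$j)], nm)))
  names(newX) <- kept3
  newX <- as.data.frame(scale(newX, design_center, design_scale))
  valid <- rowSums(!is.finite(as.matrix(newX))) == 0
  map <- matrix(NA_real_, length(ri), length(ci))
  if (any(valid)) {
    pc <- cbind(xy$x[cells$j], xy$y[cells$i])
    pr <- stage("map_predict",
                predict_gwr(gm_opt, pc[valid, , drop = FALSE],
                            newX[valid, , drop = FALSE]))
    map[cbind(match(cells$i[valid], ri), match(cells$j[valid], ci))] <- pr$pred
  }
  truth <- scene$grids$true_fcc[ri, ci]

  dist_bins <- stage("distribution", fcc_distribution(map))
  val <- stage("validation", validate_against_plots(
    map, plots, scene$cell_size * st, scene$x0, scene$y0))
  map_ok <- !is.na(map)
  map_truth <- eval_metrics(truth[map_ok], map[map_ok])
  s_opt <- gwr_summary(gm_opt); s_base <- gwr_summary(gm_base)
  improvements <- list(
    gwr_r2 = report_improvements(s_base$r2, s_opt$r2, "delta_over_before", "gain"),
    gwr_rmse = report_improvements(s_base$rmse, s_opt$rmse, "delta_over_before", "error"),
    gwr_aicc = report_improvements(s_base$aicc, s_opt$aicc, "delta_over_before", "error"),
    footprint_r2 = report_improvements(
      ms$comparison$r2[!ms$comparison$optimized],
      ms$comparison$r2[ms$comparison$optimized], "delta_over_after", "gain"),
    footprint_rmse = report_improvements(
      ms$comparison$rmse[!ms$comparison$optimized],
      ms$comparison$rmse[ms$comparison$optimized], "delta_over_before", "error")
  )
  report <- structure(list(
    seed = config$seed, config_hash = config_hash(unclass(config)),
    n_footprints = nrow(fp), n_plots = nrow(plots),
    footprint_features = kept_fp, best_model = ms$best_type,
    footprint_comparison = ms$comparison,
    regional_covariates = kept3,
    selection = list(importance = imp, pearson = ps, vif = vf, normality = na),
    gwr = list(optimized = s_opt, unoptimized = s_base,
               bandwidth_profile = sel$profile),
    improvements = improvements,
    fcc_distribution = as.list(dist_bins),
    plot_validation = val,
    map_truth_r2 = map_truth$r2, map_truth_r2_score = map_truth$r2_score,
    map_truth_rmse = map_truth$rmse,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    map_full <- map
    write_grid_tiff(map_full, file.path(out_dir, "fcc_map.tif"),
                    scene$cell_size * st, scene$x0, scene$y0, scene$epsg)
    write.csv(fp, file.path(out_dir, "footprint_predictions.csv"),
              row.names = FALSE)
    write.csv(ms$comparison, file.path(out_dir, "model_comparison.csv"),
              row.names = FALSE)
    report_json <- report
    report_json$selection <- lapply(report_json$selection, as.data.frame)
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  attr(report, "model") <- best_fit
  attr(report, "gwr_model") <- gm_opt
  attr(report, "map") <- map
  attr(report, "scene") <- scene
  attr(report, "footprints") <- fp
  attr(report, "plots") <- plots
  report
}
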