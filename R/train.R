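#' Tune, evaluate and select the footprint-scale learner
#'
#' For each enabled learner type, evaluates a default-parameter baseline by
#' leave-one-out cross-validation, runs Bayesian optimization with objective
#' = LOOCV RMSE, and re-evaluates the tuned incumbent. The winner is the
#' tuned model with the highest LOOCV R-squared; ties break toward lower
#' RMSE, then lower MAR.
#'
#' @param features data.frame of predictors (typically the selected
#'   footprint features at the plot locations).
#' @param target measured canopy closure at the plots.
#' @param models learner types to enable, subset of `knn`, `rfr`, `gbrt`.
#' @param budget total BO evaluations per model (initial design included),
#'   default 50 for desk-scale runs; 1000 is the conventional full budget.
#' @param n_init initial design size, default 10.
#' @param seed integer seed covering BO and the tree learners.
#' @param spaces optional named list overriding [default_search_space()].
#' @return list of class `model_selection`: `best` (tuned `model_spec` of the
#'   winner), `reports` (per-type tuned `eval_report`s), `baselines`
#'   (default-parameter reports), `histories` (per-type `bo_history`),
#'   `comparison` (long data.frame of R2/RMSE/P/MAR before and after tuning).
#' @export
train_and_select <- function(features, target, models = c("knn", "rfr", "gbrt"),
                             budget = 50, n_init = 10, seed = 1L,
                             spaces = NULL) {
  stopifnot(length(models) >= 1)
  features <- as.data.frame(features)
  reports <- list(); baselines <- list(); histories <- list()
  for (m in models) {
    base_spec <- list(type = m, params = default_params(m))
    baselines[[m]] <- loocv_evaluate(base_spec, features, target, seed = seed)
    space <- if (!is.null(spaces[[m]])) spaces[[m]] else default_search_space(m)
    obj <- function(params) {
      loocv_evaluate(list(type = m, params = params), features, target,
                     seed = seed)$rmse
    }
    histories[[m]] <- bo_minimize(obj, space, budget = budget, n_init = n_init,
                                  seed = split_seed(seed, match(m, models)))
    tuned_spec <- list(type = m, params = histories[[m]]$best_params)
    reports[[m]] <- loocv_evaluate(tuned_spec, features, target, seed = seed)
  }
  score <- function(r) c(r$r2, -r$rmse, -r$mar)
  ord <- order(vapply(reports, function(r) r$r2, 0),
               -vapply(reports, function(r) r$rmse, 0),
               -vapply(reports, function(r) r$mar, 0),
               decreasing = TRUE)
  winner <- models[ord[1]]
  comparison <- do.call(rbind, lapply(models, function(m) {
    rbind(
      data.frame(model = m, optimized = FALSE,
                 r2 = baselines[[m]]$r2, rmse = baselines[[m]]$rmse,
                 p_accuracy = baselines[[m]]$p_accuracy, mar = baselines[[m]]$mar),
      data.frame(model = m, optimized = TRUE,
                 r2 = reports[[m]]$r2, rmse = reports[[m]]$rmse,
                 p_accuracy = reports[[m]]$p_accuracy, mar = reports[[m]]$mar)
    )
  }))
  structure(list(best = reports[[winner]]$model_spec, best_type = winner,
                 reports = reports, baselines = baselines,
                 histories = histories, comparison = comparison,
                 seed = seed),
            class = "model_selection")
}

#' Predict canopy closure for every footprint
#'
#' Applies a fitted learner to a footprint table and appends a
#' `predicted_fcc` column, clamped to \[0, 1\] (canopy closure is a
#' proportion). Deterministic given the fitted model.
#'
#' @param model a fitted `canopy_learner` (see [fit_learner()]).
#' @param table a `footprint_table` containing the model's feature columns.
#' @return the table with `predicted_fcc` filled in.
#' @export
predict_footprints <- function(model, table) {
  miss <- setdiff(model$feature_names, names(table))
  if (length(miss) > 0)
    stop(sprintf("footprint table lacks feature column(s): %s",
                 paste(miss, collapse = ", ")))
  table$predicted_fcc <- clamp01(predict_learner(model, table))
  table
}
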