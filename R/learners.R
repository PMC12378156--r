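## Footprint-scale base learners behind a single fit/predict surface.
## model_spec = list(type = "knn" | "rfr" | "gbrt" | "mean", params = list()).
## "mean" is the intercept-only baseline (predicts the training mean); it
## doubles as a probe that makes leave-one-out fold exclusion observable.
## Parameter names follow the conventional estimator vocabulary:
##   rfr / gbrt: n_estimators, max_depth, min_samples_leaf
##   knn:        n_neighbors, weights ("uniform" | "distance")
## The GBRT learning rate is fixed at 0.1 and not tuned.

#' Default hyperparameters per learner type
#' @param type learner type.
#' @return named list of defaults.
#' @export
default_params <- function(type) {
  switch(type,
    mean = list(),
    knn  = list(n_neighbors = 5, weights = "uniform"),
    rfr  = list(n_estimators = 100, max_depth = 0, min_samples_leaf = 5),
    gbrt = list(n_estimators = 100, max_depth = 3, min_samples_leaf = 1),
    stop(sprintf("unknown learner type '%s'", type))
  )
}

#' Default hyperparameter search space per learner type
#'
#' Integer ranges: `n_estimators` 50-1000, `max_depth` 2-20,
#' `min_samples_leaf` 1-10, `n_neighbors` 2-20; KNN `weights` is categorical
#' over uniform/distance.
#'
#' @param type learner type.
#' @return a search space: list of parameter definitions usable by
#'   [bo_minimize()].
#' @export
default_search_space <- function(type) {
  switch(type,
    knn = list(
      list(name = "n_neighbors", type = "int", lower = 2, upper = 20),
      list(name = "weights", type = "cat", values = c("uniform", "distance"))
    ),
    rfr = ,
    gbrt = list(
      list(name = "n_estimators", type = "int", lower = 50, upper = 1000),
      list(name = "max_depth", type = "int", lower = 2, upper = 20),
      list(name = "min_samples_leaf", type = "int", lower = 1, upper = 10)
    ),
    stop(sprintf("unknown learner type '%s'", type))
  )
}

#' Fit a footprint-scale learner
#'
#' @param model_spec list with `type` and `params` (missing entries filled
#'   from [default_params()]).
#' @param features data.frame of numeric predictors.
#' @param target numeric response.
#' @param seed integer seed (tree learners).
#' @return fitted learner object of class `canopy_learner`.
#' @export
fit_learner <- function(model_spec, features, target, seed = 1L) {
  type <- model_spec$type
  p <- utils::modifyList(default_params(type), model_spec$params %||% list())
  features <- as.data.frame(features)
  X <- as.matrix(features)
  fit <- switch(type,
    mean = list(ybar = mean(target), n = length(target)),
    knn = {
      mu <- colMeans(X); sdev <- apply(X, 2, stats::sd)
      sdev[sdev == 0] <- 1
      list(X = scale(X, mu, sdev), y = target, mu = mu, sd = sdev,
           k = p$n_neighbors, weights = p$weights)
    },
    rfr = ranger::ranger(
      x = X, y = target, num.trees = p$n_estimators,
      max.depth = p$max_depth, min.node.size = p$min_samples_leaf,
      seed = seed, num.threads = 1
    ),
    gbrt = xgboost::xgb.train(
      data = xgboost::xgb.DMatrix(X, label = target, nthread = 1),
      nrounds = p$n_estimators,
      params = list(eta = 0.1, max_depth = p$max_depth,
                    min_child_weight = p$min_samples_leaf,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      verbose = 0
    ),
    stop(sprintf("unknown learner type '%s'", type))
  )
  structure(list(type = type, params = p, fit = fit,
                 feature_names = colnames(X)),
            class = "canopy_learner")
}

#' @rdname fit_learner
#' @param object a fitted `canopy_learner`.
#' @param newdata data.frame containing the training feature columns.
#' @return numeric predictions.
#' @export
predict_learner <- function(object, newdata) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss) > 0)
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  switch(object$type,
    mean = rep(object$fit$ybar, nrow(X)),
    knn = {
      f <- object$fit
      Xs <- scale(X, f$mu, f$sd)
      apply(Xs, 1, function(q) {
        d <- sqrt(colSums((t(f$X) - q)^2))
        k <- min(f$k, length(d))
        idx <- order(d)[seq_len(k)]
        if (identical(f$weights, "distance")) {
          dd <- d[idx]
          if (any(dd < 1e-12)) return(mean(f$y[idx[dd < 1e-12]]))
          w <- 1 / dd
          sum(w * f$y[idx]) / sum(w)
        } else mean(f$y[idx])
      })
    },
    rfr = stats::predict(object$fit, data = X, num.threads = 1)$predictions,
    gbrt = stats::predict(object$fit, newdata = xgboost::xgb.DMatrix(X, nthread = 1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
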