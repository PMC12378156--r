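#' Accuracy metrics for canopy-closure predictions
#'
#' The four headline metrics, as ratios of sums of squares about the observed
#' mean: `R2 = sum((yhat - ybar)^2) / sum((y - ybar)^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, `P = (1 - RMSE/ybar) * 100`,
#' `MAR = mean(|y - yhat|)`. `ybar` is the mean of the *observed* values:
#' using the mean prediction would break the perfect-prediction identity
#' `R2 = 1`.
#'
#' Two R-squared variants are reported. `r2` is the sum-of-squares ratio
#' above, which equals the conventional coefficient of determination only
#' for least-squares fits; for other predictors it rewards prediction
#' variance and is not monotone in fit quality. `r2_score` is the
#' conventional `1 - RSS/TSS` that regression toolkits report; paired
#' tuned-versus-default comparisons should use `r2_score` (or RMSE).
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return named list `r2, r2_score, rmse, p_accuracy, mar, ybar, n`;
#'   `p_accuracy` is `NA` with a warning when `ybar` is 0.
#' @export
eval_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ybar <- mean(y)
  tss <- sum((y - ybar)^2)
  r2 <- sum((yhat - ybar)^2) / tss
  r2_score <- 1 - sum((y - yhat)^2) / tss
  rmse <- sqrt(mean((y - yhat)^2))
  p <- if (abs(ybar) < 1e-12) {
    warning("observed mean is zero; P undefined")
    NA_real_
  } else (1 - rmse / ybar) * 100
  list(r2 = r2, r2_score = r2_score, rmse = rmse, p_accuracy = p,
       mar = mean(abs(y - yhat)), ybar = ybar, n = length(y))
}

#' Leave-one-out cross-validation of a learner
#'
#' For each row i, fits the learner on the remaining n - 1 rows and predicts
#' row i; scores the held-out predictions with [eval_metrics()].
#'
#' @param model_spec list with `type` (`"knn"`, `"rfr"`, `"gbrt"`) and
#'   `params` (see [fit_learner()]).
#' @param features data.frame of predictors.
#' @param target numeric response.
#' @param seed seed forwarded to each fold's fit.
#' @return an `eval_report`: the [eval_metrics()] list plus `predictions`
#'   (per-fold held-out predictions) and `model_spec`.
#' @export
loocv_evaluate <- function(model_spec, features, target, seed = 1L) {
  features <- as.data.frame(features)
  n <- nrow(features)
  stopifnot(n >= 3, length(target) == n)
  preds <- vapply(seq_len(n), function(i) {
    fit <- fit_learner(model_spec, features[-i, , drop = FALSE], target[-i],
                       seed = seed)
    predict_learner(fit, features[i, , drop = FALSE])
  }, numeric(1))
  out <- eval_metrics(target, preds)
  out$predictions <- preds
  out$model_spec <- model_spec
  class(out) <- "eval_report"
  out
}
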