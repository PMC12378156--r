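#' Geographically weighted regression configuration
#'
#' @param kernel `"bisquare"` (compact support, the pipeline default) or
#'   `"gaussian"` (`w = exp(-d^2 / theta^2)`).
#' @param bandwidth_mode `"adaptive_neighbors"` (bandwidth is the distance to
#'   the k-th nearest training point, k the tunable) or `"fixed_distance"`
#'   (bandwidth theta in meters).
#' @param bandwidth k (adaptive) or theta in meters (fixed); `NULL` to select
#'   by [select_bandwidth()].
#' @param search_bounds length-2 bounds for bandwidth selection; defaults to
#'   `[p + 2, n]` neighbors (adaptive) or the data's distance range (fixed).
#' @param search_tol convergence tolerance of the golden-section search
#'   (fixed-distance mode).
#' @param ridge_fallback ridge added to a singular local system (with a
#'   warning); 0 turns the fallback into an error.
#' @return list of class `gwr_config`.
#' @export
gwr_config <- function(kernel = c("bisquare", "gaussian"),
                       bandwidth_mode = c("adaptive_neighbors", "fixed_distance"),
                       bandwidth = NULL, search_bounds = NULL,
                       search_tol = 0.01, ridge_fallback = 1e-8) {
  structure(list(kernel = match.arg(kernel),
                 bandwidth_mode = match.arg(bandwidth_mode),
                 bandwidth = bandwidth, search_bounds = search_bounds,
                 search_tol = search_tol, ridge_fallback = ridge_fallback),
            class = "gwr_config")
}

#' Spatial kernel weights
#'
#' Gaussian: `w = exp(-d^2/theta^2)`. Bisquare: `w = (1 - (d/theta)^2)^2`
#' for `d < theta`, else 0. Weights are in \[0, 1\] with `w(0) = 1`.
#'
#' @param d numeric vector of Euclidean distances (projected meters).
#' @param theta bandwidth in the same units, strictly positive.
#' @param kernel `"gaussian"` or `"bisquare"`.
#' @return numeric weight vector.
#' @export
kernel_weights <- function(d, theta, kernel = c("bisquare", "gaussian")) {
  kernel <- match.arg(kernel)
  if (!is.finite(theta) || theta <= 0) stop("bandwidth theta must be positive")
  if (kernel == "gaussian") exp(-d^2 / theta^2)
  else ifelse(d < theta, (1 - (d / theta)^2)^2, 0)
}

## theta at a location: fixed bandwidth, or distance to the k-th nearest
## training point (self included when the location is a training point)
resolve_theta <- function(d, config) {
  if (config$bandwidth_mode == "fixed_distance") return(config$bandwidth)
  k <- as.integer(round(config$bandwidth))
  k <- min(max(k, 1L), length(d))
  th <- sort(d, partial = k)[k]
  max(th, 1e-9)
}

## solve one local weighted system; `ridged` flags a singular system that
## needed the ridge fallback (callers aggregate these into one warning)
local_wls <- function(Xd, y, w, ridge) {
  A <- crossprod(Xd, Xd * w)
  b <- crossprod(Xd, w * y)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(beta)) {
    if (ridge <= 0) stop("singular local system and ridge_fallback = 0")
    ridged <- TRUE
    # ridge relative to the system's scale, escalating until solvable
    scale <- max(mean(diag(A)), 1e-12)
    lam <- ridge * scale
    repeat {
      Ar <- A + diag(lam, ncol(Xd))
      beta <- tryCatch(solve(Ar, b), error = function(e) NULL)
      if (!is.null(beta) || lam > 1e6 * scale) break
      lam <- lam * 1e4
    }
    if (is.null(beta)) stop("singular local system; ridge escalation failed")
    A <- Ar
  }
  list(beta = as.numeric(beta), A = A, ridged = ridged)
}

#' Fit a geographically weighted regression
#'
#' At every training location i, solves the locally weighted least-squares
#' system `a(i) = (X' W_i X)^{-1} X' W_i y` with kernel weights centred on
#' that location, and accumulates fitted values, residuals, the hat-matrix
#' diagonal and trace, AICc, and kernel-weighted local R-squared.
#'
#' @param X numeric matrix or data.frame of predictors (no intercept column;
#'   one is added).
#' @param y numeric response.
#' @param coords two-column matrix of projected coordinates in meters;
#'   longitude/latitude input is rejected.
#' @param config a [gwr_config()] with a resolved `bandwidth`.
#' @return list of class `gwr_model`: `coef` (n x (p+1)), `fitted`,
#'   `residuals`, `hat_diag`, `trace_S`, `rss`, `sigma2`, `aicc`,
#'   `local_r2`, plus the training data and configuration.
#' @export
fit_gwr <- function(X, y, coords, config) {
  X <- as.matrix(X); coords <- as.matrix(coords)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, nrow(coords) == n, ncol(coords) == 2)
  if (n <= p + 2) stop("need n > p + 2 observations")
  if (is.null(config$bandwidth)) stop("config$bandwidth is not set")
  if (all(abs(coords[, 1]) <= 360) && all(abs(coords[, 2]) <= 90) &&
      max(dist(coords[seq_len(min(n, 20)), ])) < 10)
    stop("coordinates look geographic (lon/lat); project to meters first")
  Xd <- cbind(`(Intercept)` = 1, X)
  coefs <- matrix(NA_real_, n, p + 1,
                  dimnames = list(NULL, colnames(Xd)))
  fitted <- numeric(n); hat_diag <- numeric(n); local_r2 <- numeric(n)
  n_ridged <- 0L
  for (i in seq_len(n)) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
    theta <- resolve_theta(d, config)
    w <- kernel_weights(d, theta, config$kernel)
    sol <- local_wls(Xd, y, w, config$ridge_fallback)
    n_ridged <- n_ridged + sol$ridged
    coefs[i, ] <- sol$beta
    fitted[i] <- sum(Xd[i, ] * sol$beta)
    xi <- Xd[i, ]
    hat_diag[i] <- as.numeric(t(xi) %*% solve(sol$A, xi)) * w[i]
    yhat_local <- as.numeric(Xd %*% sol$beta)
    ybar_w <- sum(w * y) / sum(w)
    denom <- sum(w * (y - ybar_w)^2)
    local_r2[i] <- if (denom > 0) 1 - sum(w * (y - yhat_local)^2) / denom else NA_real_
  }
  if (n_ridged > 0)
    warning(sprintf("%d of %d local systems were singular; ridge fallback applied",
                    n_ridged, n), call. = FALSE)
  res <- y - fitted
  rss <- sum(res^2)
  trS <- sum(hat_diag)
  aicc <- tryCatch(aicc_score(rss, n, trS), error = function(e) NA_real_)
  structure(list(coef = coefs, fitted = fitted, residuals = res,
                 hat_diag = hat_diag, trace_S = trS, rss = rss,
                 sigma2 = rss / n, aicc = aicc, local_r2 = local_r2,
                 X = X, y = y, coords = coords, config = config,
                 bandwidth = config$bandwidth),
            class = "gwr_model")
}

#' Corrected AIC of a linear smoother
#'
#' `AICc = 2 n ln(sigma) + n ln(2 pi) + n (n + tr S) / (n - 2 - tr S)` with
#' `sigma = sqrt(RSS / n)` — the standard GWR form that charges the trace of
#' the hat matrix as effective parameters. Strictly increasing in RSS at
#' fixed n and tr S.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param trace_S hat-matrix trace (effective parameters).
#' @return the AICc value.
#' @export
aicc_score <- function(rss, n, trace_S) {
  if (n - 2 - trace_S <= 0)
    stop("trace(S) >= n - 2: bandwidth infeasible for AICc")
  sigma <- sqrt(rss / n)
  2 * n * log(sigma) + n * log(2 * pi) + n * (n + trace_S) / (n - 2 - trace_S)
}

#' Golden-section bandwidth selection by AICc
#'
#' Minimizes the AICc of [fit_gwr()] over the bandwidth by golden-section
#' search: continuous over theta in fixed-distance mode, over rounded
#' neighbor counts with memoized evaluations (ties to the smaller bandwidth)
#' in adaptive mode. Infeasible bandwidths score `+Inf`. A minimizer at a
#' search bound is returned with a boundary warning.
#'
#' @inheritParams fit_gwr
#' @param config a [gwr_config()]; its `bandwidth` is ignored.
#' @param verbose print evaluations.
#' @return list with `bandwidth`, `aicc`, `profile` (data.frame of evaluated
#'   bandwidths and AICc), and `boundary` (logical).
#' @export
select_bandwidth <- function(X, y, coords, config, verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  adaptive <- config$bandwidth_mode == "adaptive_neighbors"
  bounds <- config$search_bounds
  if (is.null(bounds)) {
    bounds <- if (adaptive) c(p + 2, n) else {
      dd <- dist(coords)
      c(min(dd[dd > 0]) * 2, max(dd))
    }
  }
  if (bounds[1] >= bounds[2]) stop("invalid search bounds")
  cache <- new.env(parent = emptyenv())
  evalb <- function(b) {
    b <- if (adaptive) as.integer(round(b)) else b
    key <- format(b, digits = 12)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- config; cfg$bandwidth <- b
    val <- tryCatch({
      fit <- fit_gwr(X, y, coords, cfg)
      if (is.na(fit$aicc)) Inf else fit$aicc
    }, error = function(e) Inf)
    cache[[key]] <- val
    if (verbose) message(sprintf("bandwidth %s -> AICc %.4f", key, val))
    val
  }
  phi <- (sqrt(5) - 1) / 2
  lo <- bounds[1]; hi <- bounds[2]
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- evalb(x1); f2 <- evalb(x2)
  tol <- if (adaptive) 1 else config$search_tol * (bounds[2] - bounds[1])
  while ((hi - lo) > tol) {
    if (f1 <= f2) {  # ties move toward the smaller bandwidth
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- evalb(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- evalb(x2)
    }
    if (adaptive && round(x1) == round(x2)) break
  }
  evalb(bounds[1]); evalb(bounds[2])
  keys <- ls(cache)
  prof <- data.frame(bandwidth = as.numeric(keys),
                     aicc = vapply(keys, function(k) cache[[k]], 0),
                     row.names = NULL)
  prof <- prof[order(prof$bandwidth), ]
  if (all(!is.finite(prof$aicc))) stop("no feasible bandwidth in the search bounds")
  fin <- prof[is.finite(prof$aicc), ]
  best <- fin[which.min(fin$aicc), ]
  boundary <- isTRUE(all.equal(best$bandwidth, as.numeric(bounds[1]))) ||
    isTRUE(all.equal(best$bandwidth, as.numeric(bounds[2])))
  if (boundary)
    warning("AICc minimized at a search bound; consider widening the bounds")
  list(bandwidth = if (adaptive) as.integer(best$bandwidth) else best$bandwidth,
       aicc = best$aicc, profile = prof, boundary = boundary)
}

#' Predict with a fitted GWR at new locations
#'
#' Refits the local coefficients from the training data at each prediction
#' location (model bandwidth, adaptive bandwidths re-resolved against the
#' training points) and evaluates the local linear predictor. Under the
#' bisquare kernel a location farther than theta from every training point
#' gets `NA` with a warning.
#'
#' @param model a `gwr_model`.
#' @param new_coords two-column matrix of prediction coordinates (meters).
#' @param new_X predictor matrix matching the training design (no intercept).
#' @param clamp clamp predictions to \[0, 1\] (canopy closure), default TRUE.
#' @return list with `pred` (numeric vector) and `coef` (local coefficients
#'   at the prediction locations).
#' @export
predict_gwr <- function(model, new_coords, new_X, clamp = TRUE) {
  new_X <- as.matrix(new_X); new_coords <- as.matrix(new_coords)
  if (ncol(new_X) != ncol(model$X))
    stop("new_X columns do not match the training design")
  Xd <- cbind(1, model$X)
  m <- nrow(new_X)
  pred <- numeric(m)
  coefs <- matrix(NA_real_, m, ncol(Xd))
  config <- model$config
  any_empty <- FALSE
  n_ridged <- 0L
  for (i in seq_len(m)) {
    d <- sqrt((model$coords[, 1] - new_coords[i, 1])^2 +
                (model$coords[, 2] - new_coords[i, 2])^2)
    theta <- resolve_theta(d, config)
    w <- kernel_weights(d, theta, config$kernel)
    if (sum(w) <= 0) {
      pred[i] <- NA_real_; any_empty <- TRUE; next
    }
    sol <- local_wls(Xd, model$y, w, config$ridge_fallback)
    n_ridged <- n_ridged + sol$ridged
    coefs[i, ] <- sol$beta
    pred[i] <- sum(c(1, new_X[i, ]) * sol$beta)
  }
  if (n_ridged > 0)
    warning(sprintf("%d of %d local prediction systems were singular; ridge fallback applied",
                    n_ridged, m), call. = FALSE)
  if (any_empty)
    warning("some prediction locations have zero kernel weight everywhere (nodata)")
  if (clamp) pred <- clamp01(pred)
  list(pred = pred, coef = coefs)
}

#' Summarize a GWR model as JSON-ready diagnostics
#'
#' @param model a `gwr_model`.
#' @return list with bandwidth, kernel, AICc, trace, global R2 and local-R2
#'   quartiles.
#' @export
gwr_summary <- function(model) {
  gof <- eval_metrics(model$y, model$fitted)
  q <- quantile(model$local_r2, c(0.25, 0.5, 0.75), na.rm = TRUE)
  list(kernel = model$config$kernel,
       bandwidth_mode = model$config$bandwidth_mode,
       bandwidth = model$bandwidth, n = length(model$y),
       trace_S = model$trace_S, aicc = model$aicc,
       r2 = gof$r2, rmse = gof$rmse, p_accuracy = gof$p_accuracy,
       mar = gof$mar,
       local_r2 = list(q25 = unname(q[1]), median = unname(q[2]),
                       q75 = unname(q[3]),
                       mean = mean(model$local_r2, na.rm = TRUE)))
}
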