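#' Random-forest importance screening
#'
#' Fits a seeded random-forest regressor (impurity importance, 500 trees by
#' default), normalizes the mean-decrease-in-impurity importances to sum 1,
#' and keeps every variable whose share is at least `threshold`. The boundary
#' is inclusive: a share exactly at the threshold survives.
#'
#' @param features data.frame / matrix of candidate predictors.
#' @param target numeric response (canopy closure).
#' @param threshold minimum importance share, default 0.05.
#' @param num_trees number of trees, default 500.
#' @param seed integer seed for the forest.
#' @return a `selection_report`: data.frame with `name`, `importance_share`,
#'   `decision`, `reason`, plus attributes `kept` (names) and `method`.
#' @export
rf_importance_select <- function(features, target, threshold = 0.05,
                                 num_trees = 500, seed = 1L) {
  features <- as.data.frame(features)
  if (nrow(features) < 10) stop("need at least 10 observations")
  if (stats::sd(target) == 0) stop("target is constant")
  all_na <- vapply(features, function(x) all(is.na(x)), logical(1))
  if (any(all_na))
    stop(sprintf("all-NaN column(s): %s", paste(names(features)[all_na], collapse = ", ")))
  dat <- cbind(features, .y = target)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                        num.trees = num_trees, importance = "impurity",
                        seed = seed)
  imp <- fit$variable.importance
  share <- pmax(imp, 0) / sum(pmax(imp, 0))
  keep <- share >= threshold
  rep <- data.frame(name = names(share), importance_share = as.numeric(share),
                    decision = ifelse(keep, "kept", "dropped"),
                    reason = ifelse(keep, "importance share >= threshold",
                                    "importance share < threshold"),
                    row.names = NULL)
  rep <- rep[order(-rep$importance_share), ]
  selection_report(rep, kept = rep$name[rep$decision == "kept"],
                   method = "rf_importance")
}

#' Pearson correlation screening
#'
#' Keeps variables with `|r| >= r_min` and a two-sided p-value below `alpha`
#' against the target (the magnitude boundary is inclusive). Zero-variance
#' variables are dropped with a reason, not an error. The screen is invariant
#' to affine rescaling of any variable.
#'
#' @inheritParams rf_importance_select
#' @param r_min minimum absolute correlation, default 0.2.
#' @param alpha significance level, default 0.01.
#' @return a `selection_report` with `pearson_r` and `p_value` columns.
#' @export
pearson_screen <- function(features, target, r_min = 0.2, alpha = 0.01) {
  features <- as.data.frame(features)
  if (nrow(features) < 5) stop("need at least 5 observations")
  rows <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      return(data.frame(name = nm, pearson_r = NA_real_, p_value = NA_real_,
                        decision = "dropped", reason = "zero variance"))
    }
    ct <- cor.test(x, target)
    keep <- abs(ct$estimate) >= r_min && ct$p.value < alpha
    data.frame(name = nm, pearson_r = unname(ct$estimate),
               p_value = ct$p.value,
               decision = if (keep) "kept" else "dropped",
               reason = if (keep) "|r| >= r_min and p < alpha"
                        else if (abs(ct$estimate) < r_min) "|r| < r_min"
                        else "not significant")
  })
  rep <- do.call(rbind, rows)
  selection_report(rep, kept = rep$name[rep$decision == "kept"],
                   method = "pearson_screen")
}

#' Iterative variance-inflation-factor filter
#'
#' Repeatedly drops the predictor with the largest VIF until all remaining
#' VIFs are at or below `max_vif`. `VIF_j = 1 / (1 - R2_j)` where `R2_j` is
#' from regressing predictor j on the others with intercept; perfect
#' collinearity gives an infinite VIF and is removed first, never a crash.
#'
#' @param features data.frame of predictors (at least two).
#' @param max_vif removal threshold, default 10.
#' @return a `selection_report` with the final `vif` per variable (`NA` for
#'   removed ones, recorded with the VIF at removal in `reason`).
#' @export
vif_filter <- function(features, max_vif = 10) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 variables")
  if (nrow(features) <= ncol(features))
    stop("need more observations than variables")
  active <- names(features)
  dropped <- list()
  repeat {
    if (length(active) < 2) break
    v <- vif_values(features[active])
    worst <- which.max(v)
    if (v[worst] <= max_vif) break
    dropped[[active[worst]]] <- v[worst]
    active <- active[-worst]
  }
  final <- if (length(active) >= 2) vif_values(features[active]) else
    setNames(rep(1, length(active)), active)
  rows <- lapply(names(features), function(nm) {
    if (nm %in% active) {
      data.frame(name = nm, vif = unname(final[nm]), decision = "kept",
                 reason = "VIF <= max_vif")
    } else {
      data.frame(name = nm, vif = NA_real_, decision = "dropped",
                 reason = sprintf("removed at VIF = %.3g", dropped[[nm]]))
    }
  })
  rep <- do.call(rbind, rows)
  selection_report(rep, kept = active, method = "vif_filter")
}

vif_values <- function(df) {
  X <- as.matrix(df)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(r^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' D'Agostino K-squared omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the omnibus
#' statistic `K2 = Z1(sqrt(b1))^2 + Z2(b2)^2`, chi-squared with 2 df under
#' normality, using the D'Agostino-Pearson transformations.
#'
#' @param x numeric vector, `n >= 20`.
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("need n >= 20")
  if (stats::sd(x) == 0) stop("constant vector is untestable")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  d <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  Z1 <- d * log(Y / a + sqrt((Y / a)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  B <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / B * (2 / B + sqrt(1 + 4 / B^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE),
       skewness = g1, kurtosis = g2)
}

#' Normality assessment with optional power transform
#'
#' Runs the omnibus skewness/kurtosis normality test on each variable. With
#' `transform = "auto"`, variables failing at `alpha` get a one-parameter
#' Yeo-Johnson power transform (maximum-likelihood lambda) and are retested;
#' the report records the transform and both test results. Histograms can be
#' exported as PNGs.
#'
#' @param variables data.frame of numeric variables, `n >= 20` each.
#' @param alpha significance level, default 0.05.
#' @param transform `"auto"` (power-transform failures) or `"none"`.
#' @param hist_dir optional directory for per-variable histogram PNGs.
#' @return a `selection_report` with `statistic`, `p_value`, `normal`
#'   (logical), `applied_transform`, `lambda`, and post-transform columns.
#' @export
normality_assess <- function(variables, alpha = 0.05, transform = "auto",
                             hist_dir = NULL) {
  variables <- as.data.frame(variables)
  if (!is.null(hist_dir)) dir.create(hist_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(variables), function(nm) {
    x <- variables[[nm]]
    if (stats::sd(x, na.rm = TRUE) == 0) stop(sprintf("constant vector '%s' is untestable", nm))
    t0 <- dagostino_test(x)
    pass0 <- t0$p_value >= alpha
    lam <- NA_real_; applied <- "none"; fam <- NA_character_
    stat <- t0$statistic; pv <- t0$p_value; pass <- pass0
    if (!pass0 && identical(transform, "auto")) {
      # Box-Cox for strictly positive variables (contains log exactly),
      # Yeo-Johnson otherwise
      fam_choice <- if (all(x > 0, na.rm = TRUE)) "bcPower" else "yjPower"
      pt <- try(car::powerTransform(x ~ 1, family = fam_choice), silent = TRUE)
      if (!inherits(pt, "try-error")) {
        fam <- fam_choice
        lam <- unname(coef(pt))
        xt <- if (fam_choice == "bcPower") car::bcPower(x, lam) else car::yjPower(x, lam)
        t1 <- dagostino_test(xt)
        applied <- "power"
        stat <- t1$statistic; pv <- t1$p_value; pass <- t1$p_value >= alpha
      }
    }
    if (!is.null(hist_dir)) {
      grDevices::png(file.path(hist_dir, paste0(nm, ".png")), 480, 360)
      graphics::hist(x, breaks = 20, main = nm, xlab = nm)
      grDevices::dev.off()
    }
    data.frame(name = nm, statistic = stat, p_value = pv, normal = pass,
               applied_transform = applied, lambda = lam,
               transform_family = fam,
               raw_statistic = t0$statistic, raw_p_value = t0$p_value,
               decision = ifelse(pass, "kept", "dropped"),
               reason = if (pass && applied == "none") "normal"
                        else if (pass) "normal after power transform"
                        else "non-normal")
  })
  rep <- do.call(rbind, rows)
  selection_report(rep, kept = rep$name[rep$decision == "kept"],
                   method = "normality_assess")
}

selection_report <- function(df, kept, method) {
  attr(df, "kept") <- kept
  attr(df, "method") <- method
  class(df) <- c("selection_report", "data.frame")
  df
}

#' Kept variable names of a selection report
#' @param report a `selection_report`.
#' @return character vector of kept variable names.
#' @export
kept_variables <- function(report) attr(report, "kept")

#' Write a selection report to JSON and CSV
#' @param report a `selection_report`.
#' @param path_base file path without extension; writes `.json` and `.csv`.
#' @return `path_base`, invisibly.
#' @export
write_selection_report <- function(report, path_base) {
  write.csv(as.data.frame(report), paste0(path_base, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(method = attr(report, "method"),
                            kept = attr(report, "kept"),
                            table = as.data.frame(report)),
                       paste0(path_base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path_base)
}
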