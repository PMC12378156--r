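## Gaussian-process Bayesian optimization of learner hyperparameters.
## Search-space grammar: a space is a list of parameter definitions,
##   list(name, type = "int" | "num" | "cat", lower/upper or values).
## Internally every parameter lives on [0,1]; integers are decoded by
## rounding (continuous relaxation), categoricals by bin, and the surrogate
## sees integers on their normalized scale and categoricals as indicator
## columns.

space_dim <- function(space) length(space)

decode_point <- function(u, space) {
  out <- list()
  for (d in seq_along(space)) {
    p <- space[[d]]
    v <- min(1 - 1e-12, max(0, u[d]))
    out[[p$name]] <- switch(p$type,
      int = as.integer(p$lower + floor(v * (p$upper - p$lower + 1))),
      num = p$lower + v * (p$upper - p$lower),
      cat = p$values[1 + floor(v * length(p$values))],
      stop("unknown parameter type"))
  }
  out
}

encode_features <- function(params, space) {
  f <- c()
  for (p in space) {
    val <- params[[p$name]]
    f <- c(f, switch(p$type,
      int = (val - p$lower) / max(1, p$upper - p$lower),
      num = (val - p$lower) / (p$upper - p$lower),
      cat = as.numeric(p$values == val)))
  }
  f
}

point_key <- function(params) paste(vapply(params, as.character, ""), collapse = "|")

## ---- Gaussian process surrogate (Matern 5/2, ARD) ----

matern52 <- function(F1, F2, ell, s2) {
  D2 <- matrix(0, nrow(F1), nrow(F2))
  for (d in seq_len(ncol(F1)))
    D2 <- D2 + outer(F1[, d], F2[, d], "-")^2 / ell[d]^2
  r <- sqrt(pmax(D2, 0))
  s2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

gp_loglik <- function(logpar, F, y) {
  q <- ncol(F)
  ell <- exp(logpar[seq_len(q)])
  s2 <- exp(logpar[q + 1]); sn2 <- exp(logpar[q + 2])
  K <- matern52(F, F, ell, s2) + diag(sn2 + 1e-10, nrow(F))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) +
               0.5 * length(y) * log(2 * pi))
}

gp_fit <- function(F, y) {
  mu <- mean(y); sdy <- stats::sd(y); if (sdy < 1e-12) sdy <- 1
  ys <- (y - mu) / sdy
  q <- ncol(F)
  init <- c(rep(log(0.3), q), log(1), log(1e-3))
  lower <- c(rep(log(0.02), q), log(1e-3), log(1e-8))
  upper <- c(rep(log(20), q), log(1e3), log(1))
  opt <- tryCatch(
    optim(init, gp_loglik, F = F, y = ys, method = "L-BFGS-B",
          lower = lower, upper = upper, control = list(maxit = 40)),
    error = function(e) list(par = init))
  ell <- exp(opt$par[seq_len(q)])
  s2 <- exp(opt$par[q + 1]); sn2 <- exp(opt$par[q + 2])
  K <- matern52(F, F, ell, s2) + diag(sn2 + 1e-10, nrow(F))
  ch <- chol(K + diag(1e-8, nrow(F)))
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(F = F, mu = mu, sdy = sdy, ell = ell, s2 = s2, sn2 = sn2,
       chol = ch, alpha = alpha)
}

gp_predict <- function(gp, Fnew) {
  Ks <- matern52(Fnew, gp$F, gp$ell, gp$s2)
  m <- as.numeric(Ks %*% gp$alpha)
  v <- backsolve(gp$chol, forwardsolve(t(gp$chol), t(Ks)))
  var <- pmax(gp$s2 - colSums(v^2), 1e-12)
  list(mean = m * gp$sdy + gp$mu, sd = sqrt(var) * gp$sdy)
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * pnorm(z) + sd * stats::dnorm(z)
}

## nearest unevaluated neighbour of a decoded point (finite spaces)
perturb_to_new <- function(params, space, seen) {
  cands <- list()
  for (p in space) {
    if (p$type == "int") {
      for (dv in c(-1L, 1L, -2L, 2L)) {
        v <- params[[p$name]] + dv
        if (v >= p$lower && v <= p$upper) {
          q <- params; q[[p$name]] <- as.integer(v); cands <- c(cands, list(q))
        }
      }
    } else if (p$type == "cat") {
      for (v in setdiff(p$values, params[[p$name]])) {
        q <- params; q[[p$name]] <- v; cands <- c(cands, list(q))
      }
    } else {
      q <- params
      q[[p$name]] <- min(p$upper, max(p$lower, params[[p$name]] +
                                        stats::rnorm(1, 0, 0.01 * (p$upper - p$lower))))
      cands <- c(cands, list(q))
    }
  }
  for (q in cands) if (!(point_key(q) %in% seen)) return(q)
  NULL
}

#' Bayesian optimization of a black-box objective
#'
#' Minimizes `objective` over a hyperparameter space with a Gaussian-process
#' surrogate (Matern-5/2, ARD; integer dimensions by continuous relaxation
#' and rounding, categoricals by indicator coding) and expected-improvement
#' acquisition. Starts from `n_init` Latin-hypercube evaluations, then
#' iterates: refit the surrogate, maximize expected improvement over a
#' random candidate set plus jittered copies of the best evaluated points,
#' evaluate, append. Duplicate proposals are perturbed to the nearest
#' unevaluated point; objectives returning non-finite values are recorded at
#' a worst-so-far penalty.
#'
#' @param objective function taking a named parameter list, returning a
#'   scalar to minimize.
#' @param space list of parameter definitions (see [default_search_space()]).
#' @param n_iter surrogate-guided evaluations after the initial design.
#'   The conventional full budget is 1000 total evaluations; desk-scale runs
#'   use far less.
#' @param n_init initial space-filling evaluations (default 20).
#' @param budget optional total budget `n_init + n_iter`; overrides `n_iter`
#'   and must be at least `n_init`.
#' @param seed integer seed for all optimizer randomness.
#' @param n_candidates acquisition candidate-set size per iteration.
#' @return a `bo_history`: list with `records` (data.frame of parameters,
#'   `y`, `iteration`, `incumbent_y`), `best_params`, `best_y`, `surrogate`
#'   (final GP hyperparameters), `seed`, `budget`.
#' @export
bo_minimize <- function(objective, space, n_iter = 1000, n_init = 20,
                        budget = NULL, seed = 1L, n_candidates = 256) {
  if (!is.null(budget)) {
    if (budget < n_init) stop("budget must be at least n_init")
    n_iter <- budget - n_init
  }
  budget <- n_init + n_iter
  D <- space_dim(space)
  with_stream_seed(seed, 11L, {
    U <- lhs::randomLHS(n_init, D)
    pts <- list(); ys <- numeric(0); keys <- character(0)
    eval_pt <- function(params) {
      y <- tryCatch(objective(params), error = function(e) NA_real_)
      if (!is.finite(y)) {
        y <- if (length(ys) && any(is.finite(ys))) max(ys[is.finite(ys)]) else 1e6
      }
      y
    }
    for (i in seq_len(n_init)) {
      p <- decode_point(U[i, ], space)
      if (point_key(p) %in% keys) {
        alt <- perturb_to_new(p, space, keys)
        if (!is.null(alt)) p <- alt
      }
      pts[[length(pts) + 1]] <- p
      keys <- c(keys, point_key(p))
      ys <- c(ys, eval_pt(p))
    }
    gp <- NULL
    for (t in seq_len(n_iter)) {
      F <- do.call(rbind, lapply(pts, encode_features, space = space))
      gp <- gp_fit(F, ys)
      Uc <- matrix(runif(n_candidates * D), n_candidates, D)
      ord <- order(ys)[seq_len(min(5, length(ys)))]
      # local jitter around incumbents sharpens the acquisition optimum
      for (b in ord) {
        ub <- vapply(seq_len(D), function(d) {
          p <- space[[d]]; val <- pts[[b]][[p$name]]
          switch(p$type,
            int = (val - p$lower + 0.5) / (p$upper - p$lower + 1),
            num = (val - p$lower) / (p$upper - p$lower),
            cat = (match(val, p$values) - 0.5) / length(p$values))
        }, numeric(1))
        J <- matrix(pmin(1, pmax(0, rep(ub, each = 8) +
                                   rnorm(8 * D, 0, 0.05))), 8, D, byrow = FALSE)
        Uc <- rbind(Uc, J)
      }
      cand <- lapply(seq_len(nrow(Uc)), function(i) decode_point(Uc[i, ], space))
      Fc <- do.call(rbind, lapply(cand, encode_features, space = space))
      pr <- gp_predict(gp, Fc)
      ei <- expected_improvement(pr$mean, pr$sd, min(ys))
      new <- !(vapply(cand, point_key, "") %in% keys)
      pick <- if (any(new)) which(new)[which.max(ei[new])] else which.max(ei)
      p <- cand[[pick]]
      if (point_key(p) %in% keys) {
        alt <- perturb_to_new(p, space, keys)
        if (!is.null(alt)) p <- alt
      }
      pts[[length(pts) + 1]] <- p
      keys <- c(keys, point_key(p))
      ys <- c(ys, eval_pt(p))
    }
    rec <- do.call(rbind, lapply(pts, function(p) as.data.frame(p, stringsAsFactors = FALSE)))
    rec$y <- ys
    rec$iteration <- seq_along(ys)
    rec$incumbent_y <- cummin(ys)
    best <- which.min(ys)
    structure(list(records = rec, best_params = pts[[best]], best_y = ys[best],
                   surrogate = if (is.null(gp)) NULL else
                     list(lengthscales = gp$ell, signal_var = gp$s2,
                          noise_var = gp$sn2),
                   seed = seed, n_init = n_init, n_iter = n_iter,
                   budget = budget),
              class = "bo_history")
  })
}

#' Write a BO trial history to CSV
#' @param history a `bo_history`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bo_history <- function(history, path) {
  write.csv(history$records, path, row.names = FALSE)
  invisible(path)
}
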