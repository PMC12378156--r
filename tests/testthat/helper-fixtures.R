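# Shared fixtures, built once per test run. Scenes are deterministic in the
# config, so caching is purely a speed measure.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

default_scene <- function() {
  cached("default_scene", function() {
    cfg <- scene_config()
    sc <- generate_scene(cfg)
    fp <- make_footprint_features(sc, cfg)
    pl <- sample_plots(sc, cfg, footprints = fp)
    list(cfg = cfg, scene = sc, footprints = fp, plots = pl)
  })
}

small_scene <- function() {
  cached("small_scene", function() {
    cfg <- scene_config(grid_rows = 64, grid_cols = 64,
                        n_footprint_tracks = 14, seed = 11L)
    sc <- generate_scene(cfg)
    fp <- make_footprint_features(sc, cfg)
    list(cfg = cfg, scene = sc, footprints = fp)
  })
}

# scene covariates sampled at footprint locations (generating design for GWR)
scene_design <- function(sc, fp) {
  X <- data.frame(
    ndvi = extract_at(sc$z$ndvi, sc$cell_size, fp$x, fp$y),
    vv_minus_vh = extract_at(sc$z$vv_minus_vh, sc$cell_size, fp$x, fp$y),
    elevation = extract_at(sc$z$elevation, sc$cell_size, fp$x, fp$y))
  list(X = X, y = fp$true_fcc, coords = cbind(fp$x, fp$y))
}

# independent brute-force weighted least squares (normal equations with an
# explicit diagonal weight matrix) -- oracle for fit_gwr
brute_wls <- function(Xd, y, w) {
  W <- diag(w)
  solve(t(Xd) %*% W %*% Xd, t(Xd) %*% W %*% y)
}

# independent pure-R co-occurrence accumulation -- oracle for the compiled
# path (per-window min-max quantization, symmetric counts, normalization)
brute_cooc <- function(win, levels, offsets) {
  lo <- min(win); hi <- max(win); span <- hi - lo
  q <- if (span < 1e-300) matrix(0L, nrow(win), ncol(win)) else
    pmin(matrix(floor((win - lo) / span * levels), nrow(win)), levels - 1)
  P <- matrix(0, levels, levels)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in seq_len(nrow(win))) for (c in seq_len(ncol(win))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(win) || c2 < 1 || c2 > ncol(win)) next
      a <- q[r, c] + 1; b <- q[r2, c2] + 1
      P[a, b] <- P[a, b] + 1; P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

# independent R implementation of windowed GLCM features (mirror padding)
brute_glcm <- function(band, window, levels, offsets) {
  h <- window %/% 2
  nr <- nrow(band); nc <- ncol(band)
  refl <- function(i, n) { i <- abs(i - 1) + 1; ifelse(i > n, 2 * n - i, i) }
  out <- lapply(1:8, function(k) matrix(NA_real_, nr, nc))
  names(out) <- c("ME", "VA", "HO", "CO", "DI", "EN", "SM", "CR")
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- band[refl((r - h):(r + h), nr), refl((c - h):(c + h), nc)]
    st <- glcm_stats(brute_cooc(win, levels, offsets))
    for (k in names(out)) out[[k]][r, c] <- st[[k]]
  }
  out
}
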