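# Independent oracles: deliberately naive implementations used only to
# check the package's vectorised code paths.

# AUC by exhaustive pair counting over all presence-absence pairs.
oracle_auc <- function(labels, scores) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# Convex hull by gift wrapping (Jarvis march), area by the shoelace formula.
oracle_hull_area_km2 <- function(x, y, units = "m") {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- start
  cur <- start
  repeat {
    nxt <- if (cur == 1) 2 else 1
    for (k in seq_len(n)) {
      if (k == cur) next
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
            (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_k > d_nxt)) nxt <- k
    }
    cur <- nxt
    if (cur == start) break
    hull <- c(hull, cur)
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (units == "m") a / 1e6 else a
}

# Balanced threshold by brute-force scan of every candidate, recomputing the
# confusion matrix per candidate.
oracle_balanced_threshold <- function(labels, scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(0.5)
  cand <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stats <- t(vapply(cand, function(t) {
    fp <- sum(scores >= t & labels == 0)
    fn <- sum(scores < t & labels == 1)
    c(err = fp + fn, gap = abs((1 - fn / n1) - (1 - fp / n0)))
  }, c(err = 0, gap = 0)))
  ord <- order(stats[, "err"], stats[, "gap"], cand)
  cand[ord[1]]
}

oracle_total_error <- function(labels, scores, t) {
  sum(scores >= t & labels == 0) + sum(scores < t & labels == 1)
}

# Friedman partial dependence by explicit row-by-row averaging of the
# booster's latent output.
oracle_partial_dependence <- function(model, predictor, eval_grid) {
  x <- model$train_x
  pd <- numeric(length(eval_grid))
  for (j in seq_along(eval_grid)) {
    tot <- 0
    for (i in seq_len(nrow(x))) {
      row <- x[i, , drop = FALSE]
      row[1, predictor] <- eval_grid[j]
      tot <- tot + predict(model$booster, xgboost::xgb.DMatrix(row),
                           outputmargin = TRUE)
    }
    pd[j] <- tot / nrow(x)
  }
  pd - mean(pd)
}

# Per-cell nearest-cell lookup by explicit index arithmetic.
oracle_extract <- function(stack, px, py) {
  g <- stack$grid
  out <- matrix(NA_real_, length(px), length(stack$layers),
                dimnames = list(NULL, names(stack$layers)))
  for (i in seq_along(px)) {
    fx <- (px[i] - g$origin_x) / g$cell_size
    fy <- (py[i] - g$origin_y) / g$cell_size
    col <- if (fx == floor(fx) && fx > 0) fx else floor(fx) + 1
    row <- if (fy == floor(fy) && fy > 0) fy else floor(fy) + 1
    if (col < 1 || col > g$n_cols || row < 1 || row > g$n_rows) next
    cell <- (row - 1) * g$n_cols + col
    for (k in seq_along(stack$layers))
      out[i, k] <- stack$layers[[k]]$values[cell]
  }
  out
}

# Small shared fixtures -------------------------------------------------------

# A tiny two-predictor stack with known values.
tiny_stack <- function(n = 10, cell = 500) {
  g <- grid_spec(n_cols = n, n_rows = n, cell_size = cell)
  a <- sdm_raster(g, seq_len(n * n) / (n * n), name = "a")
  b <- sdm_raster(g, rev(seq_len(n * n)) * 1.0, name = "b")
  predictor_stack(list(a, b))
}

# A linearly separable toy table: label = 1 iff x1 > 0, margin 1.
separable_toy <- function(n = 200, seed = 42) {
  set.seed(seed)
  x1 <- c(stats::runif(n / 2, 1, 2), stats::runif(n / 2, -2, -1))
  data.frame(label = as.integer(x1 > 0), x1 = x1,
             x2 = stats::rnorm(n))
}

# A quick, fully fitted small model on the separable toy.
toy_model <- function(n = 200, n_trees = 60, seed = 42) {
  tab <- separable_toy(n, seed)
  suppressWarnings(fit_niche(tab, hp = hyperparameters(
    n_trees = n_trees, max_nodes = 4, min_cases = 5,
    learning_rate = 0.3, subsample = 1), seed = seed))
}
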