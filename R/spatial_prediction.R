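#' Score a model to the regular grid
#'
#' Applies a fitted model to attributed scoring points (one per unmasked cell
#' centre from [make_scoring_grid]), yielding the point-level relative index
#' of occurrence (RIO) before smoothing.
#'
#' @param model a `niche_model`.
#' @param scoring_points data.frame with the model's predictor columns (plus
#'   `cell`, `x`, `y` bookkeeping).
#' @return the input data.frame with a `score` column in `[0, 1]`.
#' @export
score_grid <- function(model, scoring_points) {
  scoring_points$score <- predict(model, scoring_points)
  scoring_points
}

#' Inverse-distance-weighted RIO surface
#'
#' Smooths point scores into a continuous raster: each cell takes the
#' weighted mean of its `k` nearest scored points with weights
#' `d^-power`; a cell whose centre coincides with a scored point takes that
#' point's score exactly. Output is clipped to `[0, 1]`.
#'
#' When the scored points are exactly the unmasked cell centres (the usual
#' case from [make_scoring_grid]), the coincident rule short-circuits the
#' neighbour search, so the surface equals the scores.
#'
#' @param points data.frame with `x`, `y`.
#' @param scores numeric vector, one per point.
#' @param grid a [grid_spec].
#' @param power IDW exponent (default 2).
#' @param k neighbours used per cell (default 12).
#' @param mask optional logical study-area mask; masked cells become `NA`.
#' @return an [sdm_raster] (`kind = "rio"`) with values in `[0, 1]`.
#' @export
idw_smooth <- function(points, scores, grid, power = 2, k = 12, mask = NULL) {
  if (!nrow(points)) stop("need at least one scored point")
  if (k < 1) stop("k must be >= 1")
  if (length(scores) != nrow(points)) stop("scores/points length mismatch")
  vals <- rep(NA_real_, n_cells(grid))
  # exact hits: points sitting on a cell centre claim that cell
  ctr_cell <- cell_from_xy(grid, points$x, points$y)
  cc_all <- cell_centers(grid, ctr_cell[!is.na(ctr_cell)])
  on_center <- !is.na(ctr_cell)
  on_center[on_center] <- abs(cc_all$x - points$x[!is.na(ctr_cell)]) < 1e-9 &
    abs(cc_all$y - points$y[!is.na(ctr_cell)]) < 1e-9
  vals[ctr_cell[on_center]] <- scores[on_center]
  todo <- which(is.na(vals))
  if (!is.null(mask)) todo <- intersect(todo, which(mask))
  if (length(todo)) {
    k_use <- min(k, nrow(points))
    cc <- cell_centers(grid, todo)
    px <- points$x; py <- points$y
    chunk <- max(1L, floor(4e6 / nrow(points)))
    for (lo in seq(1, length(todo), by = chunk)) {
      hi <- min(lo + chunk - 1L, length(todo))
      idx <- lo:hi
      d2 <- outer(cc$x[idx], px, "-")^2 + outer(cc$y[idx], py, "-")^2
      for (r in seq_along(idx)) {
        nn <- order(d2[r, ])[seq_len(k_use)]
        dr <- sqrt(d2[r, nn])
        if (dr[1] == 0) { vals[todo[idx[r]]] <- scores[nn[1]]; next }
        w <- dr^(-power)
        vals[todo[idx[r]]] <- sum(w * scores[nn]) / sum(w)
      }
    }
  }
  if (!is.null(mask)) vals[!mask] <- NA
  vals <- pmin(1, pmax(0, vals))
  sdm_raster(grid, vals, kind = "rio", name = "RIO")
}

#' Balanced presence/absence threshold
#'
#' The score cutoff that converts a continuous RIO surface into a binary
#' presence map: among candidate thresholds (0, 1, and the midpoints of
#' consecutive sorted unique scores), returns the one minimising total error
#' (false positives + false negatives). Ties break to the candidate that
#' best balances sensitivity and specificity, then to the lowest threshold.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in `[0, 1]`.
#' @return threshold in `[0, 1]`.
#' @export
balanced_threshold <- function(labels, scores) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1) return(0.5)  # no information in the scores
  cand <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
  best_t <- NA_real_; best_err <- Inf; best_gap <- Inf
  for (t in cand) {
    pred <- scores >= t
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    err <- fp + fn
    gap <- abs((1 - fn / n1) - (1 - fp / n0))  # |sensitivity - specificity|
    if (err < best_err || (err == best_err && gap < best_gap)) {
      best_t <- t; best_err <- err; best_gap <- gap
    }
  }
  best_t
}

#' Threshold a RIO raster to a binary presence map
#'
#' @param rio an [sdm_raster] with values in `[0, 1]`.
#' @param threshold cutoff in `[0, 1]`; cells with RIO >= threshold become 1.
#' @param season,year optional labels carried on the map.
#' @return a `binary_map` ([sdm_raster] subclass) with a `threshold`
#'   attribute; nodata cells stay `NA`.
#' @export
binarize <- function(rio, threshold, season = NULL, year = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  v <- as.numeric(rio$values >= threshold)
  v[is.na(rio$values)] <- NA
  r <- sdm_raster(rio$grid, v, kind = "binary", name = rio$name)
  attr(r, "threshold") <- threshold
  attr(r, "season") <- season
  attr(r, "year") <- year
  class(r) <- c("binary_map", class(r))
  r
}

#' Total predicted presence area
#'
#' Presence pixels times pixel area. At the default 500-m cells each pixel
#' is 0.25 km^2, so four presence pixels make 1 km^2.
#'
#' @param map a `binary_map` (or any raster of 0/1 values).
#' @return area in km^2.
#' @export
predicted_area <- function(map) {
  sum(map$values == 1, na.rm = TRUE) * map$grid$pixel_area
}

#' Validate a RIO surface against independent fixes
#'
#' Residual per fix is `1 - RIO` at the fix's cell: 0 where the surface
#' predicted certain presence, 1 where it predicted certain absence. Small
#' mean residuals over an independent year's telemetry indicate good spatial
#' transfer.
#'
#' @param rio an [sdm_raster] RIO surface.
#' @param points data.frame of independent fixes with `x`, `y`.
#' @param year label recorded in the report.
#' @return list (`validation_report`): `mean_residual`, `sd_residual`
#'   (population SD), `n_points`, `year`.
#' @export
mean_residuals <- function(rio, points, year = NA) {
  cells <- cell_from_xy(rio$grid, points$x, points$y)
  ok <- !is.na(cells) & !is.na(rio$values[pmax(cells, 1L)])
  if (sum(ok) < 2) stop("need >= 2 fixes inside the grid")
  res <- 1 - rio$values[cells[ok]]
  m <- mean(res)
  structure(list(mean_residual = m,
                 sd_residual = sqrt(mean((res - m)^2)),
                 n_points = sum(ok), year = year),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Mean residual (1 - RIO) = %.2f +/- %.2f over %d fixes%s\n",
              x$mean_residual, x$sd_residual, x$n_points,
              if (is.na(x$year)) "" else sprintf(" (%s)", x$year)))
  invisible(x)
}
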