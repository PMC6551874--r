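#' Describe a synthetic environmental layer
#'
#' Layer recipes drive [generate_landscape]. Continuous layers are spatially
#' autocorrelated Gaussian random fields rescaled to the requested moments;
#' distance layers are Euclidean distances from randomly placed features
#' (communities, roads, coastline stand-ins); categorical layers are produced
#' by [generate_landcover].
#'
#' @param name layer name (unique within a landscape).
#' @param kind `"continuous"` or `"distance"`.
#' @param mean,sd target mean and standard deviation, layer units
#'   (continuous only; `sd = 0` yields a constant field).
#' @param correlation_length spatial autocorrelation scale in metres (the
#'   Gaussian smoothing kernel's sigma).
#' @param n_features number of random features (distance layers).
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(name, kind = c("continuous", "distance"),
                       mean = 0, sd = 1, correlation_length = 5000,
                       n_features = 3) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be >= 0")
  if (correlation_length <= 0) stop("correlation_length must be positive")
  structure(list(name = name, kind = kind, mean = mean, sd = sd,
                 correlation_length = correlation_length,
                 n_features = n_features),
            class = "layer_spec")
}

# Gaussian random field: smooth white noise with a Gaussian kernel (sigma in
# cells) by FFT circular convolution, then rescale to exact sample moments.
.gaussian_field <- function(n_rows, n_cols, sigma_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma_cells <= 0) return(z)
  gx <- stats::dnorm(pmin(0:(n_cols - 1), n_cols - (0:(n_cols - 1))),
                     sd = sigma_cells)
  gy <- stats::dnorm(pmin(0:(n_rows - 1), n_rows - (0:(n_rows - 1))),
                     sd = sigma_cells)
  k <- outer(gy, gx)
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  sm
}

.rescale_moments <- function(v, mean, sd) {
  if (sd == 0) return(rep(mean, length(v)))
  s <- stats::sd(v)
  if (s == 0) return(rep(mean, length(v)))
  (v - base::mean(v)) / s * sd + mean
}

#' Generate a synthetic predictor landscape
#'
#' Builds one raster per [layer_spec] on a shared grid. Continuous layers are
#' Gaussian random fields with the requested mean, standard deviation and
#' autocorrelation length; distance layers place `n_features` random feature
#' points and rasterise the Euclidean distance to the nearest one. The result
#' is bit-identical for a fixed `(grid, layers, seed)`.
#'
#' @param grid a [grid_spec].
#' @param layers list of [layer_spec] recipes (at least one).
#' @param seed integer root seed; each layer derives a child seed from it.
#' @return a [predictor_stack].
#' @export
generate_landscape <- function(grid, layers, seed) {
  if (!length(layers)) stop("need at least one layer")
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate layer names: ", paste(unique(nm[duplicated(nm)]),
                                          collapse = ", "))
  out <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    ls <- layers[[k]]
    set.seed(derive_seed(seed, paste0("layer:", ls$name)))
    if (ls$kind == "continuous") {
      f <- .gaussian_field(grid$n_rows, grid$n_cols,
                           ls$correlation_length / grid$cell_size)
      # matrix is row-major from the bottom once transposed to cell order
      v <- as.numeric(t(f))
      out[[k]] <- sdm_raster(grid, .rescale_moments(v, ls$mean, ls$sd),
                             kind = "continuous", name = ls$name)
    } else {
      feats <- data.frame(
        x = stats::runif(ls$n_features, grid$origin_x,
                         grid$origin_x + grid$n_cols * grid$cell_size),
        y = stats::runif(ls$n_features, grid$origin_y,
                         grid$origin_y + grid$n_rows * grid$cell_size))
      r <- distance_to_features(grid, feats, name = ls$name)
      attr(r, "features") <- feats
      out[[k]] <- r
    }
  }
  predictor_stack(out)
}

#' Generate a categorical land-cover raster
#'
#' Slices a single autocorrelated random field at its sample quantiles so the
#' realised class shares match the requested proportions (classes are coded
#' `1..K` in the order given). Quantile slicing keeps classes spatially
#' contiguous at the correlation scale, mimicking an ecotype map.
#'
#' @param grid a [grid_spec].
#' @param class_proportions numeric vector summing to 1 (tolerance 1e-6);
#'   names, if present, are kept as class labels.
#' @param correlation_length autocorrelation scale, metres.
#' @param seed integer seed.
#' @return an [sdm_raster] of kind `"categorical"` with a `class_labels`
#'   attribute.
#' @export
generate_landcover <- function(grid, class_proportions,
                               correlation_length = 5000, seed = 1) {
  p <- class_proportions
  if (!length(p)) stop("empty proportion vector")
  if (any(p < 0) || any(p > 1)) stop("proportions must be in [0, 1]")
  if (abs(sum(p) - 1) > 1e-6) stop("class proportions must sum to 1")
  set.seed(derive_seed(seed, "landcover"))
  f <- .gaussian_field(grid$n_rows, grid$n_cols,
                       correlation_length / grid$cell_size)
  v <- as.numeric(t(f))
  br <- stats::quantile(v, probs = cumsum(p)[-length(p)], names = FALSE)
  codes <- findInterval(v, br, left.open = TRUE) + 1L
  r <- sdm_raster(grid, codes, kind = "categorical", name = "landcover")
  attr(r, "class_labels") <-
    if (!is.null(names(p))) names(p) else as.character(seq_along(p))
  r
}

## ---- niche ground truth ---------------------------------------------------

#' One term of a synthetic niche response
#'
#' @param layer predictor layer name.
#' @param type `"step"` (suitability jumps by `weight` where the layer
#'   exceeds `threshold`) or `"linear"` (`weight` per standardised layer
#'   unit).
#' @param threshold step location, layer units (step terms).
#' @param weight contribution on the latent suitability scale.
#' @param season_weight optional named numeric: per-season multiplier of
#'   `weight` (seasons not listed get 1).
#' @return a `niche_term` list.
#' @export
niche_term <- function(layer, type = c("step", "linear"), threshold = 0,
                       weight = 1, season_weight = NULL) {
  type <- match.arg(type)
  structure(list(layer = layer, type = type, threshold = threshold,
                 weight = weight, season_weight = season_weight),
            class = "niche_term")
}

#' Define a synthetic niche (the simulation's ground truth)
#'
#' Terms combine additively on a latent suitability scale; occupancy
#' probability of a cell is proportional to `exp(suitability)`. Threshold
#' (step) terms emulate the sharp response ranges that partial-dependence
#' plots recover from fitted models.
#'
#' @param ... [niche_term] objects.
#' @return a `niche_spec` list.
#' @export
niche_spec <- function(...) {
  terms <- list(...)
  if (!length(terms)) stop("need at least one term")
  structure(list(terms = terms), class = "niche_spec")
}

#' Evaluate niche suitability over a stack
#'
#' @param stack a [predictor_stack].
#' @param niche a [niche_spec].
#' @param season season name used for per-term season weights.
#' @return numeric latent suitability per cell (finite everywhere).
#' @export
niche_suitability <- function(stack, niche, season = NULL) {
  suit <- numeric(n_cells(stack$grid))
  for (tm in niche$terms) {
    if (!tm$layer %in% layer_names(stack))
      stop("stack is missing layer '", tm$layer, "' referenced by the niche")
    v <- stack$layers[[tm$layer]]$values
    w <- tm$weight
    if (!is.null(tm$season_weight) && !is.null(season) &&
        season %in% names(tm$season_weight))
      w <- w * tm$season_weight[[season]]
    suit <- suit + switch(tm$type,
      step = w * as.numeric(v > tm$threshold),
      linear = w * (v - mean(v, na.rm = TRUE)) /
        max(stats::sd(v, na.rm = TRUE), .Machine$double.eps))
  }
  suit[!is.finite(suit)] <- 0
  suit
}

#' Simulate GPS telemetry from a known niche
#'
#' Draws fixes on a regular schedule (`fix_interval_hours`, default 8 h, i.e.
#' 1095 fixes per animal per non-leap year) for each animal. Each fix's cell
#' is an independent draw from the stack's unmasked cells with probability
#' proportional to `exp(suitability)` for the fix's season; the fix location
#' is the cell centre plus uniform within-cell jitter, so point-in-cell
#' extraction is unambiguous. Fixes are exchangeable by design (no movement
#' autocorrelation): the downstream models treat them as independent
#' presences.
#'
#' @param stack a [predictor_stack].
#' @param niche a [niche_spec] (ground truth).
#' @param n_animals number of collared animals.
#' @param start_date,end_date inclusive date range (`Date` or yyyy-mm-dd).
#' @param fix_interval_hours hours between fixes; must divide 24.
#' @param seasons season table from [season_definitions] used to attribute
#'   each fix.
#' @param seed integer seed; deterministic output.
#' @return data.frame (`telemetry_set`): `animal_id`, `timestamp` (POSIXct
#'   UTC), `x`, `y` (metres), `lon`, `lat`, `season`, `season_year`, `cell`.
#' @export
simulate_telemetry <- function(stack, niche, n_animals = 1,
                               start_date, end_date,
                               fix_interval_hours = 8,
                               seasons = season_definitions(), seed = 1) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("empty date range")
  if (24 %% fix_interval_hours != 0)
    stop("fix interval must divide 24 hours")
  n_days <- as.integer(end_date - start_date) + 1L
  n_fix <- n_days * (24L %/% fix_interval_hours)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  times <- t0 + (seq_len(n_fix) - 1L) * fix_interval_hours * 3600

  sa <- assign_season(times, seasons)
  eligible <- which(stack$mask)
  # per-season occupancy distribution over eligible cells
  season_probs <- lapply(unique(sa$season), function(s) {
    w <- exp(niche_suitability(stack, niche, season = s)[eligible])
    w / sum(w)
  })
  names(season_probs) <- unique(sa$season)

  set.seed(derive_seed(seed, "telemetry"))
  cs <- stack$grid$cell_size
  out <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    cells <- integer(n_fix)
    for (s in names(season_probs)) {
      idx <- which(sa$season == s)
      cells[idx] <- sample(eligible, length(idx), replace = TRUE,
                           prob = season_probs[[s]])
    }
    ctr <- cell_centers(stack$grid, cells)
    x <- ctr$x + stats::runif(n_fix, -cs / 2, cs / 2)
    y <- ctr$y + stats::runif(n_fix, -cs / 2, cs / 2)
    ll <- xy_to_lonlat(stack$grid, x, y)
    out[[a]] <- data.frame(animal_id = sprintf("A%03d", a),
                           timestamp = times, x = x, y = y,
                           lon = ll$lon, lat = ll$lat,
                           season = sa$season, season_year = sa$season_year,
                           cell = cells)
  }
  res <- do.call(rbind, out)
  class(res) <- c("telemetry_set", "data.frame")
  res
}
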