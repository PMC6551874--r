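#' Assemble a run configuration
#'
#' One place for the constants a full run shares: season table, holdout
#' fraction, degrees-to-km constant, repeated-use cutoff, hyperparameters
#' and the root seed. Defaults are the package's standard analysis settings
#' (six-season calendar, 20% holdout, 0.25 km^2 pixels implied by the grid,
#' 111.5 km/degree, `min_years = 5`).
#'
#' A land-cover layer must stay out of the model's predictor set — selection
#' against land cover is a post-hoc analysis, and including the layer as a
#' covariate would make the selection ratios circular. `run_seasonal_model`
#' enforces this by refusing stacks whose layers include
#' `landcover_layer` unless `allow_landcover_predictor` is set.
#'
#' @param seasons season table ([season_definitions]).
#' @param holdout_fraction test fraction withheld before fitting.
#' @param km_per_deg degrees-to-km reporting constant.
#' @param min_years repeated-use cutoff in years.
#' @param hp a [hyperparameters] object.
#' @param landcover_layer name reserved for the land-cover raster.
#' @param allow_landcover_predictor override the exclusion check.
#' @param seed root seed; every stage derives its own child seed.
#' @return a `run_config` list.
#' @export
run_config <- function(seasons = season_definitions(),
                       holdout_fraction = 0.20, km_per_deg = 111.5,
                       min_years = 5, hp = hyperparameters(),
                       landcover_layer = "landcover",
                       allow_landcover_predictor = FALSE, seed = 1) {
  structure(list(seasons = seasons, holdout_fraction = holdout_fraction,
                 km_per_deg = km_per_deg, min_years = min_years, hp = hp,
                 landcover_layer = landcover_layer,
                 allow_landcover_predictor = allow_landcover_predictor,
                 seed = as.integer(seed)),
            class = "run_config")
}

.check_landcover_excluded <- function(stack, config) {
  if (config$landcover_layer %in% layer_names(stack) &&
      !config$allow_landcover_predictor)
    stop("stack contains the land-cover layer '", config$landcover_layer,
         "'; land cover is a post-hoc selection analysis, not a predictor ",
         "(set allow_landcover_predictor = TRUE to override)",
         call. = FALSE)
}

.write_manifest <- function(dir, files, seed) {
  manifest <- data.frame(file = files,
                         md5 = vapply(file.path(dir, files), function(f)
                           as.character(tools::md5sum(f)), character(1)))
  attr(manifest, "seed") <- seed
  utils::write.csv(cbind(manifest, seed = seed),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Run one pooled seasonal distribution model
#'
#' End-to-end for a single season pooled across years: build the
#' presence/pseudo-absence training table, withhold the holdout fraction,
#' fit the boosted model, score the regular grid, smooth to a RIO surface,
#' and threshold it at the model's balanced threshold. Deterministic per
#' `(config, seed)`.
#'
#' @param stack a [predictor_stack] (must not include the land-cover layer;
#'   see [run_config]).
#' @param telemetry telemetry data.frame with seasonal attribution.
#' @param season season name.
#' @param config a [run_config].
#' @param out_dir optional directory; when given, artifacts (training table,
#'   report JSON, importance and partial-dependence CSVs, RIO and binary
#'   `.asc` rasters) are written with an md5 manifest.
#' @return list: `model`, `training`, `rio`, `binary`, `report`,
#'   `importance`, `pd_top` (partial dependence of the top predictor).
#' @export
run_seasonal_model <- function(stack, telemetry, season,
                               config = run_config(), out_dir = NULL) {
  .check_landcover_excluded(stack, config)
  if (is.null(telemetry)) stop("stage telemetry_prep: telemetry is missing")
  tab <- build_training_table(stack, telemetry, season,
                              seed = derive_seed(config$seed, "training"))
  sp <- split_train_test(tab, fraction = config$holdout_fraction,
                         seed = derive_seed(config$seed, "split"))
  model <- fit_niche(sp$train, sp$test, hp = config$hp,
                     seed = derive_seed(config$seed, "fit"))
  sg <- make_scoring_grid(stack)
  sg <- score_grid(model, sg)
  rio <- idw_smooth(sg[, c("x", "y")], sg$score, stack$grid,
                    mask = stack$mask)
  bmap <- binarize(rio, model$balanced_threshold, season = season)
  top <- names(which.max(model$importance))
  pd_top <- partial_dependence(model, top)
  out <- list(model = model, training = tab, rio = rio, binary = bmap,
              report = model$report, importance = model$importance,
              pd_top = pd_top, season = season)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "training.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(model$report, list(importances = as.list(model$importance))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(predictor = attr(pd_top, "predictor"),
                                value = pd_top$value, pd = pd_top$pd),
                     file.path(out_dir, "partial_dependence.csv"),
                     row.names = FALSE)
    write_ascii_grid(rio, file.path(out_dir, "rio.asc"))
    write_ascii_grid(bmap, file.path(out_dir, "binary.asc"))
    out$manifest <- .write_manifest(
      out_dir, c("training.csv", "report.json", "partial_dependence.csv",
                 "rio.asc", "binary.asc"), config$seed)
  }
  out
}

#' Run the annual migration analysis for a season
#'
#' Fits one model per season-year (spring or fall), thresholds each year's
#' RIO surface, and derives the migration analytics: the annual area and
#' deviation table, the composite frequency map and the repeated-use map.
#' Years with no fixes are skipped with a warning.
#'
#' @param stack a [predictor_stack].
#' @param telemetry telemetry data.frame.
#' @param season `"spring"` or `"fall"`.
#' @param config a [run_config].
#' @param years years to model; default every season-year present in the
#'   telemetry.
#' @return list: `maps` (named per-year `binary_map`s), `table` (area and
#'   deviation table), `composite`, `repeated_use`, `models`.
#' @export
run_annual_migration <- function(stack, telemetry, season = c("spring", "fall"),
                                 config = run_config(), years = NULL) {
  season <- match.arg(season)
  .check_landcover_excluded(stack, config)
  fixes <- telemetry[telemetry$season == season, , drop = FALSE]
  if (is.null(years))
    years <- sort(unique(fixes$season_year))
  have <- vapply(years, function(yr)
    sum(fixes$season_year == yr) > 0, logical(1))
  if (any(!have)) {
    warning("skipping year(s) with no fixes: ",
            paste(years[!have], collapse = ", "))
    years <- years[have]
  }
  if (length(years) < 2)
    stop("need >= 2 years of fixes for the annual migration analysis")
  sg0 <- make_scoring_grid(stack)
  maps <- list(); models <- list()
  for (yr in years) {
    tab <- build_training_table(stack, telemetry, season, year = yr,
                                seed = derive_seed(config$seed,
                                                   paste0("train", yr)))
    sp <- split_train_test(tab, fraction = config$holdout_fraction,
                           seed = derive_seed(config$seed,
                                              paste0("split", yr)))
    model <- fit_niche(sp$train, sp$test, hp = config$hp,
                       seed = derive_seed(config$seed, paste0("fit", yr)))
    sg <- score_grid(model, sg0)
    rio <- idw_smooth(sg[, c("x", "y")], sg$score, stack$grid,
                      mask = stack$mask)
    maps[[as.character(yr)]] <- binarize(rio, model$balanced_threshold,
                                         season = season, year = yr)
    models[[as.character(yr)]] <- model
  }
  tab <- area_table(maps, fixes, km_per_deg = config$km_per_deg)
  comp <- composite_frequency(maps)
  ru <- repeated_use_areas(comp, min_years = min(config$min_years,
                                                 length(maps)))
  list(maps = maps, table = tab, composite = comp, repeated_use = ru,
       models = models, season = season)
}
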