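#' Reference synthetic scenario with one driving predictor
#'
#' The package's standard demonstration and validation scenario: a 60 x 60 km
#' landscape (120 x 120 cells at 500 m) with one driving layer
#' (`snow_day_fraction`, mean 0.5, sd 0.15, 5-km autocorrelation) whose
#' effect on latent suitability is a step of `contrast` units above the
#' threshold `t = 0.7`, plus an uninformative continuous layer (`pet`) and an
#' uninformative distance layer (`dist_community`). Roughly a tenth of the
#' landscape lies above the threshold, so pseudo-absences are mostly drawn
#' from unsuitable ground and the fitted model's discrimination, importance
#' ranking and partial-dependence threshold can all be checked against the
#' known truth.
#'
#' Telemetry is simulated for a full non-leap year at the 8-h fix cadence
#' (1095 fixes per animal); the modelled season is winter (Dec-Mar), giving
#' roughly 363 presences per animal, so the default 14 animals yield about
#' 5,000 presences and, by density matching, a comparable pseudo-absence
#' count.
#'
#' @param seed integer root seed (landscape, telemetry and sampling all
#'   derive child seeds from it).
#' @param n_animals number of simulated animals (default 14).
#' @param grid_size grid edge in cells (default 120).
#' @param contrast latent-suitability step height (default 10).
#' @return list: `stack`, `niche`, `telemetry`, `season` (`"winter"`),
#'   `driver` (`"snow_day_fraction"`), `threshold` (0.7), `grid`.
#' @export
synthetic_scenario <- function(seed = 1, n_animals = 14, grid_size = 120,
                               contrast = 10) {
  g <- grid_spec(n_cols = grid_size, n_rows = grid_size, cell_size = 500)
  t0 <- 0.7
  layers <- list(
    layer_spec("snow_day_fraction", mean = 0.5, sd = 0.15,
               correlation_length = 5000),
    layer_spec("pet", mean = 300, sd = 50, correlation_length = 4000),
    layer_spec("dist_community", kind = "distance", n_features = 3))
  stack <- generate_landscape(g, layers, seed = derive_seed(seed, "scenario"))
  niche <- niche_spec(niche_term("snow_day_fraction", "step",
                                 threshold = t0, weight = contrast))
  telemetry <- simulate_telemetry(stack, niche, n_animals = n_animals,
                                  start_date = "2011-01-01",
                                  end_date = "2011-12-31",
                                  seed = derive_seed(seed, "scenario_tel"))
  list(stack = stack, niche = niche, telemetry = telemetry,
       season = "winter", driver = "snow_day_fraction", threshold = t0,
       grid = g)
}
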