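#' Mean observed position of a set of fixes
#'
#' Arithmetic mean and standard deviation of the unprojected decimal-degree
#' coordinates, the per-season / per-year summary whose year-to-year
#' deviations quantify geographic shifts in migration.
#'
#' @param fixes data.frame with `lon`, `lat` (decimal degrees).
#' @return list: `mean_lon`, `mean_lat`, `sd_lon`, `sd_lat`, `n`.
#' @export
mean_position <- function(fixes) {
  if (!nrow(fixes)) stop("empty fix set")
  list(mean_lon = mean(fixes$lon), mean_lat = mean(fixes$lat),
       sd_lon = if (nrow(fixes) > 1) stats::sd(fixes$lon) else 0,
       sd_lat = if (nrow(fixes) > 1) stats::sd(fixes$lat) else 0,
       n = nrow(fixes))
}

#' Positional deviation in kilometres
#'
#' Converts the difference between an annual mean coordinate and the pooled
#' mean to signed kilometres at a fixed 111.5 km per degree on both axes
#' (the reporting convention for this study region; pass
#' `cosine_correct = TRUE` to scale longitude by `cos(latitude)` instead).
#'
#' Sign conventions follow the cardinal-letter rendering: longitude
#' deviations are west-positive (annual west of pooled is positive, rendered
#' "W"; east renders "E"), latitude deviations north-positive. Longitudes
#' may be given signed (negative = west) or as positive degrees west; the
#' two differ only by sign and are detected from the sign of the input.
#'
#' @param annual_deg annual mean coordinate, decimal degrees.
#' @param pooled_deg pooled-model mean coordinate, decimal degrees.
#' @param axis `"lon"` or `"lat"`.
#' @param km_per_deg kilometres per degree (default 111.5).
#' @param cosine_correct if TRUE and `axis = "lon"`, multiply by
#'   `cos(ref_lat)`.
#' @param ref_lat latitude used by the cosine correction.
#' @return signed deviation in km (positive = west for longitude, north for
#'   latitude).
#' @export
deviation_km <- function(annual_deg, pooled_deg, axis = c("lon", "lat"),
                         km_per_deg = 111.5, cosine_correct = FALSE,
                         ref_lat = 67) {
  axis <- match.arg(axis)
  if (!is.finite(annual_deg) || !is.finite(pooled_deg))
    stop("coordinates must be finite")
  scale <- km_per_deg
  if (axis == "lon" && cosine_correct) scale <- scale * cos(ref_lat * pi / 180)
  if (axis == "lat") return((annual_deg - pooled_deg) * scale)
  # west-positive: with degrees-west input (positive), larger = further west
  if (annual_deg >= 0 && pooled_deg >= 0) (annual_deg - pooled_deg) * scale
  else (pooled_deg - annual_deg) * scale      # signed input (negative = west)
}

#' Render a signed deviation with its cardinal letter
#'
#' @param dev_km signed deviation from [deviation_km].
#' @param axis `"lon"` or `"lat"`.
#' @param digits decimals (default 1, the reporting convention).
#' @return string such as `"88.0 E"` or `"42.4 S"`.
#' @export
format_deviation <- function(dev_km, axis = c("lon", "lat"), digits = 1) {
  axis <- match.arg(axis)
  letter <- if (axis == "lon") { if (dev_km >= 0) "W" else "E" }
            else { if (dev_km >= 0) "N" else "S" }
  sprintf("%.*f %s", digits, abs(dev_km), letter)
}

#' Sum annual binary maps into a composite frequency map
#'
#' Per-cell count, across years, of binary presence predictions; high counts
#' mark areas predicted as used in many years — the repeated-use migratory
#' corridors.
#'
#' @param maps list of `binary_map` objects on one grid (one season).
#' @return a `composite_map` ([sdm_raster] subclass) of integer counts with
#'   an `n_years` attribute.
#' @export
composite_frequency <- function(maps) {
  if (!length(maps)) stop("need at least one map")
  g <- maps[[1]]$grid
  for (m in maps)
    if (!identical(unclass(m$grid)[1:5], unclass(g)[1:5]))
      stop("all maps must share one grid_spec")
  counts <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$values; v[is.na(v)] <- 0; v
  }))
  r <- sdm_raster(g, counts, kind = "composite", name = "years_present")
  attr(r, "n_years") <- length(maps)
  class(r) <- c("composite_map", class(r))
  r
}

#' Repeated-use areas from a composite map
#'
#' Thresholds a composite frequency map at a minimum number of years,
#' identifying pixels predicted present in at least `min_years` of the
#' annual models (default 5): the favoured migratory habitat.
#'
#' @param composite a `composite_map`.
#' @param min_years minimum years predicted present, in
#'   `[1, n_years]`.
#' @return a `binary_map`.
#' @export
repeated_use_areas <- function(composite, min_years = 5) {
  ny <- attr(composite, "n_years")
  if (min_years < 1 || min_years > ny)
    stop("min_years must be in [1, ", ny, "]")
  r <- sdm_raster(composite$grid,
                  as.numeric(composite$values >= min_years),
                  kind = "binary", name = "repeated_use")
  attr(r, "threshold") <- min_years
  class(r) <- c("binary_map", class(r))
  r
}

#' Annual area and deviation table
#'
#' Builds the per-year summary for a migratory season: predicted area of
#' each annual binary map, mean observed position (with SD) of that year's
#' fixes, and signed deviations from the pooled mean observed position in
#' km. The pooled row (deviation blank) is appended last.
#'
#' @param maps named list of `binary_map` objects, names = years.
#' @param fixes telemetry data.frame with `lon`, `lat`, `season_year`.
#' @param km_per_deg degrees-to-km constant (default 111.5).
#' @return data.frame with one row per year plus a pooled row: `year`,
#'   `predicted_area_km2`, `mean_lon`, `sd_lon`, `dev_ew_km`, `dev_ew`,
#'   `mean_lat`, `sd_lat`, `dev_ns_km`, `dev_ns`.
#' @export
area_table <- function(maps, fixes, km_per_deg = 111.5) {
  years <- names(maps)
  if (is.null(years) || any(!nzchar(years)))
    stop("maps must be a named list (names = years)")
  pooled <- mean_position(fixes)
  rows <- lapply(years, function(yr) {
    fy <- fixes[fixes$season_year == as.integer(yr), , drop = FALSE]
    if (!nrow(fy)) stop("no fixes for year ", yr)
    mp <- mean_position(fy)
    dew <- deviation_km(mp$mean_lon, pooled$mean_lon, "lon",
                        km_per_deg = km_per_deg)
    dns <- deviation_km(mp$mean_lat, pooled$mean_lat, "lat",
                        km_per_deg = km_per_deg)
    data.frame(year = yr,
               predicted_area_km2 = predicted_area(maps[[yr]]),
               mean_lon = mp$mean_lon, sd_lon = mp$sd_lon,
               dev_ew_km = dew, dev_ew = format_deviation(dew, "lon"),
               mean_lat = mp$mean_lat, sd_lat = mp$sd_lat,
               dev_ns_km = dns, dev_ns = format_deviation(dns, "lat"))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(
    year = "pooled", predicted_area_km2 = NA,
    mean_lon = pooled$mean_lon, sd_lon = pooled$sd_lon,
    dev_ew_km = NA, dev_ew = "",
    mean_lat = pooled$mean_lat, sd_lat = pooled$sd_lat,
    dev_ns_km = NA, dev_ns = ""))
  rownames(tab) <- NULL
  tab
}
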