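#' Published Western Arctic Herd seasonal position and area table
#'
#' Annual and pooled (2010-2017) spring and fall summaries for the Western
#' Arctic caribou herd, northwest Alaska, as reported for the herd's
#' distribution models: predicted area (km^2), mean observed longitude
#' (degrees west, positive) and latitude with SDs, and the printed
#' deviations from the pooled means rendered with cardinal letters. Shipped
#' as plain CSV so the deviation arithmetic ([deviation_km]) can be
#' exercised against real reported values.
#'
#' @return data.frame with columns `season`, `year` (`"pooled"` for the
#'   pooled rows), `predicted_area_km2`, `mean_lon_w`, `sd_lon`, `dev_ew`,
#'   `mean_lat`, `sd_lat`, `dev_ns`.
#' @export
wah_mean_positions <- function() {
  utils::read.csv(system.file("extdata", "wah_mean_positions.csv",
                              package = "migrasdm"),
                  stringsAsFactors = FALSE)
}

#' Published Western Arctic Herd land-cover availability and use table
#'
#' Per-class available area and predicted spring/fall use areas (km^2,
#' pooled models and means of annual models) for the herd's study region,
#' with the reported selection ratios. Input for [selection_index] and
#' [rank_selection].
#'
#' @return data.frame, one row per land-cover class.
#' @export
wah_landcover_areas <- function() {
  utils::read.csv(system.file("extdata", "wah_landcover_areas.csv",
                              package = "migrasdm"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
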