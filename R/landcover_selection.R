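#' Tabulate predicted use by land-cover class
#'
#' Cross-tabulates a binary presence map against a categorical land-cover
#' raster on the same grid: per class, the presence-pixel count times the
#' pixel area. Classes with no predicted presence report 0.
#'
#' @param map a `binary_map`.
#' @param landcover a categorical [sdm_raster] (integer codes; optional
#'   `class_labels` attribute).
#' @return named numeric vector of use areas (km^2), one per land-cover
#'   class present in the raster.
#' @export
tabulate_use <- function(map, landcover) {
  if (!identical(unclass(map$grid)[1:5], unclass(landcover$grid)[1:5]))
    stop("map and landcover must share one grid_spec")
  codes <- sort(unique(landcover$values[!is.na(landcover$values)]))
  labels <- attr(landcover, "class_labels")
  use <- vapply(codes, function(cd)
    sum(map$values == 1 & landcover$values == cd, na.rm = TRUE),
    numeric(1)) * map$grid$pixel_area
  names(use) <- if (!is.null(labels) && length(labels) >= max(codes))
    labels[codes] else as.character(codes)
  use
}

#' Available area by land-cover class
#'
#' @param landcover a categorical [sdm_raster].
#' @param mask optional logical study-area mask.
#' @return named numeric vector of available areas (km^2).
#' @export
available_area <- function(landcover, mask = NULL) {
  v <- landcover$values
  if (!is.null(mask)) v[!mask] <- NA
  codes <- sort(unique(v[!is.na(v)]))
  labels <- attr(landcover, "class_labels")
  av <- vapply(codes, function(cd) sum(v == cd, na.rm = TRUE), numeric(1)) *
    landcover$grid$pixel_area
  names(av) <- if (!is.null(labels) && length(labels) >= max(codes))
    labels[codes] else as.character(codes)
  av
}

#' Land-cover selection indices (use vs. availability)
#'
#' The classical selection ratio: the percentage of predicted presence
#' falling in each cover class divided by that class's percentage of the
#' available study area. Values above 1 indicate selection for the class,
#' below 1 avoidance. Reported values are rounded to 2 decimals; the
#' `index_raw` column keeps full precision (the availability-weighted mean
#' of the raw indices is exactly 1).
#'
#' @param use_areas named numeric vector of per-class use areas (km^2).
#' @param available_areas named numeric vector of per-class available areas
#'   (km^2); every use class must be present.
#' @return data.frame (`selection_table`): `class`, `available_km2`,
#'   `use_km2`, `index` (2 dp), `index_raw`, `selected` (index > 1).
#' @export
selection_index <- function(use_areas, available_areas) {
  if (sum(use_areas) <= 0) stop("total use must be positive")
  if (sum(available_areas) <= 0) stop("total availability must be positive")
  missing_cls <- setdiff(names(use_areas), names(available_areas))
  if (length(missing_cls))
    stop("class(es) in use but not in availability: ",
         paste(missing_cls, collapse = ", "))
  cls <- names(available_areas)
  use <- setNames(numeric(length(cls)), cls)
  use[names(use_areas)] <- use_areas
  p_use <- use / sum(use)
  p_avail <- available_areas / sum(available_areas)
  raw <- ifelse(p_avail > 0, p_use / p_avail, NA)
  structure(data.frame(class = cls,
                       available_km2 = as.numeric(available_areas),
                       use_km2 = as.numeric(use),
                       index = round(raw, 2),
                       index_raw = as.numeric(raw),
                       selected = !is.na(raw) & raw > 1,
                       row.names = NULL),
            class = c("selection_table", "data.frame"))
}

#' Rank land-cover classes by selection
#'
#' Orders classes by descending selection index, ties broken by descending
#' use area — the ranking used to report which cover types a herd selects
#' during migration.
#'
#' @param table a `selection_table` from [selection_index].
#' @return the table reordered, with a `rank` column.
#' @export
rank_selection <- function(table) {
  if (!nrow(table)) stop("empty selection table")
  ord <- order(-table$index_raw, -table$use_km2)
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
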