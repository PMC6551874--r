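#' Seasonal date ranges
#'
#' The six biologically relevant caribou seasons used throughout the package:
#' spring (Apr 1 - May 27), calving (May 28 - Jun 14), insect relief
#' (Jun 15 - Jul 14), late summer (Jul 15 - Aug 31), fall (Sep 1 - Nov 30)
#' and winter (Dec 1 - Mar 31, wrapping the calendar year). Together they
#' partition the year with no gaps or overlaps.
#'
#' @return data.frame with columns `season`, `start` and `end` (month-day
#'   strings `"mm-dd"`).
#' @export
season_definitions <- function() {
  data.frame(
    season = c("spring", "calving", "insect_relief", "late_summer",
               "fall", "winter"),
    start = c("04-01", "05-28", "06-15", "07-15", "09-01", "12-01"),
    end   = c("05-27", "06-14", "07-14", "08-31", "11-30", "03-31"),
    stringsAsFactors = FALSE)
}

.md_num <- function(md) {
  p <- strsplit(md, "-", fixed = TRUE)
  vapply(p, function(q) as.integer(q[1]) * 100L + as.integer(q[2]),
         integer(1))
}

#' Assign fixes to seasons
#'
#' Maps timestamps to the unique season containing their calendar date. A
#' season that wraps the calendar year (winter: December through March) is
#' attributed to the year it began, so January-March fixes carry the previous
#' year as `season_year` and each winter stays contiguous.
#'
#' @param timestamps `POSIXct`, `Date`, or strings parseable by [as.Date].
#' @param seasons season table from [season_definitions] (must partition the
#'   year).
#' @return data.frame with columns `season` and `season_year`.
#' @export
assign_season <- function(timestamps, seasons = season_definitions()) {
  d <- tryCatch(as.Date(timestamps, tz = "UTC"),
                error = function(e) NA)
  if (anyNA(d)) stop("unparseable timestamp(s)")
  md <- as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  yr <- as.integer(format(d, "%Y"))
  out_season <- rep(NA_character_, length(d))
  out_year <- yr
  s0 <- .md_num(seasons$start); s1 <- .md_num(seasons$end)
  for (k in seq_len(nrow(seasons))) {
    if (s0[k] <= s1[k]) {
      hit <- md >= s0[k] & md <= s1[k]
    } else {                      # wraps the new year
      hit <- md >= s0[k] | md <= s1[k]
      out_year[hit & md <= s1[k]] <- yr[hit & md <= s1[k]] - 1L
    }
    out_season[hit] <- seasons$season[k]
  }
  if (anyNA(out_season))
    stop("season definitions do not cover all dates")
  data.frame(season = out_season, season_year = out_year)
}

#' Minimum convex hull area of a point set
#'
#' Area of the minimum convex polygon containing the points, the quantity
#' that scales the pseudo-absence count relative to the study-area extent.
#' Uses the Andrew/Graham hull from [grDevices::chull] and the shoelace
#' formula.
#'
#' @param x,y planar coordinates.
#' @param units units of `x`/`y`: `"m"` (default) or `"km"`.
#' @return hull area in km^2.
#' @export
convex_hull_area <- function(x, y, units = c("m", "km")) {
  units <- match.arg(units)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) stop("degenerate hull: need >= 3 distinct points")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) stop("degenerate hull: points are collinear")
  hx <- pts[h, 1]; hy <- pts[h, 2]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (units == "m") a / 1e6 else a
}

#' Pseudo-absence sample size for density matching
#'
#' Number of random pseudo-absences that keeps background density consistent
#' with presence density across seasons and years: presences times the ratio
#' of the study-area extent to the minimum convex hull area of the presences,
#' rounded to the nearest integer (minimum 1). This prevents sparse seasons
#' from being swamped by background points.
#'
#' @param n_presences presence count (> 0).
#' @param study_area study-area extent, km^2.
#' @param hull_area presence minimum convex hull area, km^2 (must not exceed
#'   `study_area`).
#' @return integer pseudo-absence count.
#' @export
pseudo_absence_count <- function(n_presences, study_area, hull_area) {
  if (n_presences <= 0 || study_area <= 0 || hull_area <= 0)
    stop("all inputs must be positive")
  if (hull_area > study_area)
    stop("hull area exceeds study area (hull outside study frame)")
  max(1L, as.integer(round(n_presences * study_area / hull_area)))
}

#' Sample pseudo-absence points
#'
#' Draws `n` cells uniformly without replacement from the study frame,
#' excluding cells that contain a presence fix (so no training cell carries
#' both labels), and returns their centres.
#'
#' @param grid a [grid_spec].
#' @param n number of pseudo-absences (>= 1).
#' @param presence_cells integer cell ids to exclude.
#' @param mask optional logical study-area mask over cells.
#' @param seed integer seed; deterministic output.
#' @return data.frame with `x`, `y`, `cell`.
#' @export
sample_pseudo_absences <- function(grid, n, presence_cells = integer(0),
                                   mask = NULL, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(mask)) mask <- rep(TRUE, n_cells(grid))
  eligible <- setdiff(which(mask), unique(presence_cells))
  if (length(eligible) < n)
    stop("fewer eligible cells (", length(eligible), ") than requested (",
         n, ")")
  set.seed(derive_seed(seed, "pseudo_absence"))
  cells <- if (length(eligible) == n) eligible else
    eligible[sample.int(length(eligible), n)]
  ctr <- cell_centers(grid, cells)
  data.frame(x = ctr$x, y = ctr$y, cell = cells)
}

#' Build a seasonal training table
#'
#' Assembles the labelled presence/pseudo-absence table for one season
#' (optionally one season-year): presences are the season's fixes, the
#' pseudo-absence count follows the density-matching rule
#' ([pseudo_absence_count]) with the study area taken from the stack's
#' unmasked extent, and both sets are attributed with every predictor layer.
#'
#' @param stack a [predictor_stack].
#' @param telemetry a telemetry data.frame ([simulate_telemetry] output or a
#'   table with `x`, `y`, `season`, `season_year`).
#' @param season season name to model.
#' @param year optional season-year filter (annual models); `NULL` pools all
#'   years.
#' @param seed integer seed for the pseudo-absence draw.
#' @return data.frame (`training_table`): `label` (1 presence / 0
#'   pseudo-absence), `season`, `season_year`, `cell`, plus one column per
#'   predictor.
#' @export
build_training_table <- function(stack, telemetry, season, year = NULL,
                                 seed = 1) {
  pres <- telemetry[telemetry$season == season, , drop = FALSE]
  if (!is.null(year))
    pres <- pres[pres$season_year == year, , drop = FALSE]
  if (!nrow(pres)) stop("no presence fixes for this season/year")
  study_area <- sum(stack$mask) * stack$grid$pixel_area
  hull <- convex_hull_area(pres$x, pres$y, units = "m")
  n_pa <- pseudo_absence_count(nrow(pres), study_area, min(hull, study_area))
  pres_cells <- cell_from_xy(stack$grid, pres$x, pres$y)
  n_eligible <- sum(stack$mask) -
    length(unique(pres_cells[!is.na(pres_cells)]))
  if (n_pa > n_eligible) {
    warning("density matching asks for ", n_pa, " pseudo-absences but only ",
            n_eligible, " presence-free cells exist; capping at that count")
    n_pa <- n_eligible
  }
  pa <- sample_pseudo_absences(stack$grid, n_pa,
                               presence_cells = pres_cells[!is.na(pres_cells)],
                               mask = stack$mask,
                               seed = derive_seed(seed, paste0(season, "_",
                                                               year %||% "pooled")))
  pres_attr <- extract_at_points(stack, pres[, c("x", "y")])
  pa_attr <- extract_at_points(stack, pa[, c("x", "y")])
  pres_attr$label <- 1L
  pa_attr$label <- 0L
  tab <- rbind(pres_attr, pa_attr)
  tab$season <- season
  tab$season_year <- if (is.null(year)) NA_integer_ else as.integer(year)
  rownames(tab) <- NULL
  class(tab) <- c("training_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/test split
#'
#' Withholds a fraction of the training table before model construction,
#' stratified by label so each class contributes `round(fraction * n_class)`
#' rows to the test subset.
#'
#' @param table labelled data.frame with a `label` column.
#' @param fraction test fraction in `[0, 1)` (default 0.20).
#' @param seed integer seed; deterministic split.
#' @return list with `train` and `test` data.frames (disjoint; union is the
#'   input).
#' @export
split_train_test <- function(table, fraction = 0.20, seed = 1) {
  labs <- unique(table$label)
  if (length(labs) < 2) stop("both classes must be present")
  set.seed(derive_seed(seed, "split"))
  test_idx <- integer(0)
  for (l in labs) {
    idx <- which(table$label == l)
    k <- round(fraction * length(idx))
    if (k > 0) test_idx <- c(test_idx, idx[sample.int(length(idx), k)])
  }
  list(train = table[setdiff(seq_len(nrow(table)), test_idx), , drop = FALSE],
       test = table[sort(test_idx), , drop = FALSE])
}
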