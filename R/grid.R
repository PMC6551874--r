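#' Define a raster grid
#'
#' A `grid_spec` describes a regular planar grid of square cells in a
#' projected, metric coordinate system. Every raster, scoring grid and
#' telemetry simulation in a run shares one `grid_spec`, so point-in-cell
#' lookups and area arithmetic are consistent across stages.
#'
#' Cell indexing convention (stated once, used everywhere): cells are 1-based,
#' row-major with row 1 at the *bottom* of the grid; cell `(i, j)` covers the
#' half-open intervals `(x0 + (j-1)*cs, x0 + j*cs]` and
#' `(y0 + (i-1)*cs, y0 + i*cs]`, except that the outer lower/left edge is
#' included so the full extent is covered. A point exactly on an interior
#' boundary therefore belongs to the cell to its lower-left.
#'
#' An optional geographic reference (`lon0`, `lat0`, `km_per_deg`) maps planar
#' metres to decimal degrees for the synthetic study frame; by convention the
#' region sits in the western hemisphere so `lon0` is negative and longitude
#' increases (towards 0) with `x`.
#'
#' @param origin_x,origin_y coordinates of the lower-left corner, metres.
#' @param n_cols,n_rows grid dimensions (positive integers).
#' @param cell_size cell edge length in metres (default 500).
#' @param lon0,lat0 decimal degrees assigned to the lower-left corner.
#' @param km_per_deg kilometres per degree used by the planar degree mapping
#'   (one constant for both axes).
#' @return An object of class `grid_spec` with fields `origin_x`, `origin_y`,
#'   `n_cols`, `n_rows`, `cell_size` and `pixel_area` (km^2 per cell;
#'   0.25 km^2 at the default 500-m cell).
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, n_cols, n_rows,
                      cell_size = 500,
                      lon0 = -163, lat0 = 65, km_per_deg = 111.5) {
  if (n_cols < 1 || n_rows < 1)
    stop("grid dimensions must be positive")
  if (cell_size <= 0)
    stop("cell_size must be positive")
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         cell_size = cell_size,
         pixel_area = (cell_size / 1000)^2,
         lon0 = lon0, lat0 = lat0, km_per_deg = km_per_deg),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows, %g-m cells (%.4g km^2/pixel)\n",
              x$n_cols, x$n_rows, x$cell_size, x$pixel_area))
  cat(sprintf("  origin (%g, %g) m; extent %g x %g km\n",
              x$origin_x, x$origin_y,
              x$n_cols * x$cell_size / 1000, x$n_rows * x$cell_size / 1000))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Cell indices containing points
#'
#' Maps planar coordinates to 1-based cell ids under the package's boundary
#' convention (interior boundaries belong to the lower-left cell). Points
#' outside the grid extent get `NA`.
#'
#' @param grid a [grid_spec].
#' @param x,y point coordinates in metres.
#' @return integer vector of cell ids (`(row-1)*n_cols + col`, row 1 at the
#'   bottom), `NA` for out-of-bounds points.
#' @export
cell_from_xy <- function(grid, x, y) {
  cs <- grid$cell_size
  fx <- (x - grid$origin_x) / cs
  fy <- (y - grid$origin_y) / cs
  col <- ceiling(fx)
  row <- ceiling(fy)
  col[fx == 0] <- 1L   # outer left edge included
  row[fy == 0] <- 1L   # outer bottom edge included
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(fx) | !is.finite(fy)
  id <- (row - 1L) * grid$n_cols + col
  id[bad] <- NA_integer_
  as.integer(id)
}

#' Cell-centre coordinates
#'
#' @param grid a [grid_spec].
#' @param cells integer cell ids; defaults to all cells.
#' @return data.frame with columns `cell`, `x`, `y` (metres).
#' @export
cell_centers <- function(grid, cells = seq_len(n_cells(grid))) {
  cells <- as.integer(cells)
  col <- (cells - 1L) %% grid$n_cols + 1L
  row <- (cells - 1L) %/% grid$n_cols + 1L
  data.frame(cell = cells,
             x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y + (row - 0.5) * grid$cell_size)
}

#' Convert planar coordinates to decimal degrees
#'
#' Uses the grid's planar degree mapping: a fixed number of kilometres per
#' degree on both axes, anchored at the grid origin. This is the inverse of
#' the convention used to express positional deviations in km (see
#' [deviation_km]).
#'
#' @param grid a [grid_spec].
#' @param x,y metres.
#' @return data.frame with `lon` (signed, negative = west) and `lat`.
#' @export
xy_to_lonlat <- function(grid, x, y) {
  m_per_deg <- grid$km_per_deg * 1000
  data.frame(lon = grid$lon0 + (x - grid$origin_x) / m_per_deg,
             lat = grid$lat0 + (y - grid$origin_y) / m_per_deg)
}

## ---- raster container -----------------------------------------------------

#' Construct a single-layer raster
#'
#' Values are stored as a numeric vector in cell-id order (row-major from the
#' bottom row); `NA` encodes nodata.
#'
#' @param grid a [grid_spec].
#' @param values numeric vector of length `n_cols * n_rows`, or a single
#'   value recycled.
#' @param kind `"continuous"`, `"categorical"` or `"distance"`.
#' @param name layer name.
#' @return an object of class `sdm_raster`.
#' @export
sdm_raster <- function(grid, values, kind = "continuous", name = "layer") {
  if (length(values) == 1L) values <- rep(values, n_cells(grid))
  if (length(values) != n_cells(grid))
    stop("values length does not match grid dimensions")
  structure(list(grid = grid, values = as.numeric(values),
                 kind = kind, name = name),
            class = "sdm_raster")
}

#' @export
print.sdm_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("sdm_raster '%s' (%s): %d x %d cells", x$name, x$kind,
              x$grid$n_cols, x$grid$n_rows))
  if (length(v))
    cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat(sprintf(", %d nodata\n", sum(is.na(x$values))))
  invisible(x)
}

#' Assemble a predictor stack
#'
#' A named collection of co-registered raster layers on one grid: the model's
#' covariate space. All layers must share the same [grid_spec]; an optional
#' study-area mask (logical, TRUE = inside) applies to every layer.
#'
#' @param layers list of [sdm_raster] objects (names taken from the rasters).
#' @param mask optional logical vector over cells, TRUE = in study area.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, mask = NULL) {
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  grid <- layers[[1]]$grid
  same <- vapply(layers, function(l) identical(unclass(l$grid)[1:5],
                                               unclass(grid)[1:5]), logical(1))
  if (!all(same)) stop("all layers must share one grid_spec")
  if (is.null(mask)) mask <- rep(TRUE, n_cells(grid))
  if (length(mask) != n_cells(grid)) stop("mask length mismatch")
  names(layers) <- nm
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers on %d x %d grid (%d masked cells)\n",
              length(x$layers), x$grid$n_cols, x$grid$n_rows, sum(!x$mask)))
  for (l in x$layers)
    cat(sprintf("  %-24s %s\n", l$name, l$kind))
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)

stack_matrix <- function(stack, cells) {
  m <- vapply(stack$layers, function(l) l$values[cells],
              numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1,
                                       dimnames = list(NULL, layer_names(stack)))
  m
}

## ---- point attribution ----------------------------------------------------

#' Attribute points with predictor values
#'
#' Looks up, for each point, the value of every stack layer at the containing
#' cell (nearest-cell rule; no interpolation, so categorical layers are safe).
#' Points outside the grid or in masked cells are dropped with a message
#' giving the count.
#'
#' @param stack a [predictor_stack].
#' @param points data.frame with columns `x`, `y` (metres).
#' @return data.frame: the input rows that fell inside the study frame, plus
#'   one column per layer and a `cell` column.
#' @export
extract_at_points <- function(stack, points) {
  cells <- cell_from_xy(stack$grid, points$x, points$y)
  inside <- !is.na(cells) & stack$mask[pmax(cells, 1L)]
  n_out <- sum(!inside)
  if (n_out > 0)
    message(n_out, " point(s) outside the study frame excluded")
  if (!any(inside)) stop("no points fall inside the grid")
  cells <- cells[inside]
  out <- points[inside, , drop = FALSE]
  out$cell <- cells
  vals <- stack_matrix(stack, cells)
  cbind(out, as.data.frame(vals))
}

#' Build the regular scoring grid
#'
#' One attributed point per unmasked cell centre: the frame the fitted model
#' is scored to before smoothing into a continuous RIO raster.
#'
#' @param stack a [predictor_stack].
#' @return data.frame with `cell`, `x`, `y` and one column per layer.
#' @export
make_scoring_grid <- function(stack) {
  cells <- which(stack$mask)
  if (!length(cells)) stop("fully masked stack")
  pts <- cell_centers(stack$grid, cells)
  cbind(pts, as.data.frame(stack_matrix(stack, cells)))
}

## ---- distance-to-feature --------------------------------------------------

#' Euclidean distance raster to the nearest feature
#'
#' Computes, for every cell centre, the shortest planar distance (metres) to
#' a set of features. Point features are given directly; line features as a
#' data.frame of ordered vertices with an `id` column, in which case distance
#' is measured to the nearest segment.
#'
#' @param grid a [grid_spec].
#' @param features data.frame with `x`, `y` (and optionally `id` for
#'   polylines).
#' @param name layer name for the returned raster.
#' @return an [sdm_raster] of kind `"distance"`.
#' @export
distance_to_features <- function(grid, features, name = "distance") {
  if (is.null(features) || nrow(features) == 0) stop("empty feature set")
  cc <- cell_centers(grid)
  if (!is.null(features$id) && length(unique(features$id)) >= 1 &&
      any(table(features$id) > 1)) {
    d2 <- rep(Inf, nrow(cc))
    for (fid in unique(features$id)) {
      seg <- features[features$id == fid, , drop = FALSE]
      if (nrow(seg) == 1L) {
        d2 <- pmin(d2, (cc$x - seg$x)^2 + (cc$y - seg$y)^2)
      } else {
        for (k in seq_len(nrow(seg) - 1L))
          d2 <- pmin(d2, .dist2_point_segment(cc$x, cc$y,
                                              seg$x[k], seg$y[k],
                                              seg$x[k + 1], seg$y[k + 1]))
      }
    }
  } else {
    d2 <- rep(Inf, nrow(cc))
    for (k in seq_len(nrow(features)))
      d2 <- pmin(d2, (cc$x - features$x[k])^2 + (cc$y - features$y[k])^2)
  }
  sdm_raster(grid, sqrt(d2), kind = "distance", name = name)
}

# squared distance from points (px,py) to segment (ax,ay)-(bx,by)
.dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

## ---- plain-text raster I/O ------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard 6-line header; rows are written top to
#' bottom. `NA` becomes the nodata value.
#'
#' @param raster an [sdm_raster].
#' @param path output file.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %g", nodata))
  m <- matrix(raster$values, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m[is.na(m)] <- nodata
  rows <- apply(m[rev(seq_len(g$n_rows)), , drop = FALSE], 1,
                function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_ascii_grid] or any conforming
#'   tool.
#' @param kind,name passed to [sdm_raster].
#' @return an [sdm_raster]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, kind = "continuous", name = "layer") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
                 tolower(vapply(hdr, `[`, character(1), 1)))
  g <- grid_spec(origin_x = kv[["xllcorner"]], origin_y = kv[["yllcorner"]],
                 n_cols = kv[["ncols"]], n_rows = kv[["nrows"]],
                 cell_size = kv[["cellsize"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m <- m[rev(seq_len(g$n_rows)), , drop = FALSE]
  v <- as.numeric(t(m))
  v[v == kv[["nodata_value"]]] <- NA
  sdm_raster(g, v, kind = kind, name = name)
}

## ---- seed derivation ------------------------------------------------------

# Stable child seeds: one root seed per run, components derive their own
# stream by hashing (root, component-name). Keeps every stage deterministic
# without sharing one RNG stream across stages.
derive_seed <- function(root, component) {
  h <- 0
  for (b in utf8ToInt(component)) h <- (h * 31 + b) %% 2147480000
  as.integer((as.numeric(root) * 7919 + h) %% 2147480000)
}
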