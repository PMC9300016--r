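#' Uniform latitude-longitude grid
#'
#' Constructs a cell-edge-registered global grid: latitude edges ascending
#' from -90 to 90 and longitude edges ascending from -180 to 180, at a
#' uniform resolution. Cell membership is half-open, `[edge_low, edge_high)`,
#' with the final edge closed, so every point maps to exactly one cell.
#'
#' @param resolution cell size in degrees; must divide 180 evenly.
#' @return An object of class `geo_grid` with components `lat_edges`,
#'   `lon_edges`, `lat_centers`, `lon_centers`, `nlat`, `nlon`, `resolution`.
#' @examples
#' g <- geo_grid(2)
#' g$nlat * g$nlon  # 16200 cells
#' @export
geo_grid <- function(resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number of degrees")
  nlat <- 180 / resolution
  nlon <- 360 / resolution
  if (abs(nlat - round(nlat)) > 1e-9 || abs(nlon - round(nlon)) > 1e-9)
    stop("`resolution` must divide 180 and 360 degrees evenly")
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  lat_edges <- seq(-90, 90, length.out = nlat + 1L)
  lon_edges <- seq(-180, 180, length.out = nlon + 1L)
  structure(list(
    lat_edges = lat_edges, lon_edges = lon_edges,
    lat_centers = (lat_edges[-1L] + lat_edges[-(nlat + 1L)]) / 2,
    lon_centers = (lon_edges[-1L] + lon_edges[-(nlon + 1L)]) / 2,
    nlat = nlat, nlon = nlon, resolution = resolution
  ), class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("geo_grid: %g deg, %d x %d cells (lat x lon)\n",
              x$resolution, x$nlat, x$nlon))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat_edges, b$lat_edges)) &&
    isTRUE(all.equal(a$lon_edges, b$lon_edges))
}

check_grid <- function(grid) {
  if (!inherits(grid, "geo_grid")) stop("expected a `geo_grid` object")
  if (any(diff(grid$lat_edges) <= 0) || any(diff(grid$lon_edges) <= 0))
    stop("grid geometry error: edges must be strictly increasing")
  invisible(grid)
}

#' Spherical cell areas
#'
#' Exact area of each grid cell on a sphere:
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\phi_2 - \sin\phi_1)}
#' where \eqn{\Delta\lambda} is the longitude width in radians and
#' \eqn{\phi_1,\phi_2} the latitude band edges. Areas depend on latitude
#' only, are symmetric about the equator, and sum to \eqn{4\pi R^2}.
#'
#' @param grid a [geo_grid()].
#' @param radius sphere radius in km (default 6371, the mean Earth radius).
#' @return Object of class `cell_areas`: the grid, an `nlat x nlon` matrix
#'   `area` in km^2, and `radius`.
#' @export
cell_areas <- function(grid, radius = 6371) {
  check_grid(grid)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number (km)")
  dlam <- diff(grid$lon_edges) * pi / 180
  if (diff(range(dlam)) > 1e-9 * mean(dlam))
    stop("grid geometry error: longitude edges are not uniform")
  band <- radius^2 * dlam[1L] * diff(sin(grid$lat_edges * pi / 180))
  structure(list(
    grid = grid,
    area = matrix(band, nrow = grid$nlat, ncol = grid$nlon),
    radius = radius
  ), class = "cell_areas")
}

#' Gridded scalar field
#'
#' A single variable on a [geo_grid()]: a value matrix (rows = latitude,
#' columns = longitude), a units string, and a validity mask. Values must be
#' finite wherever valid; non-negative quantities (export, NPP, fishing
#' intensity, euphotic depth) are checked against their units.
#'
#' @param grid a [geo_grid()].
#' @param values numeric matrix `nlat x nlon` (or a scalar, recycled).
#' @param units one of `"mg C m-2 day-1"`, `"h km-2 yr-1"`, `"degC"`, `"m"`,
#'   or any other units string (unchecked).
#' @param valid logical matrix of the same shape; default all `TRUE`.
#' @return Object of class `gridded_field`.
#' @export
gridded_field <- function(grid, values, units, valid = NULL) {
  check_grid(grid)
  if (length(values) == 1L)
    values <- matrix(values, grid$nlat, grid$nlon)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nlat, grid$nlon)))
    stop("`values` must be an nlat x nlon matrix matching the grid")
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.matrix(valid)
  if (!is.logical(valid) || !all(dim(valid) == dim(values)))
    stop("`valid` must be a logical matrix matching `values`")
  valid <- valid & !is.na(values)
  if (any(!is.finite(values[valid])))
    stop("field values must be finite wherever valid")
  nonneg_units <- c("mg C m-2 day-1", "h km-2 yr-1", "m")
  if (units %in% nonneg_units && any(values[valid] < 0))
    stop(sprintf("field in units '%s' must be non-negative where valid", units))
  structure(list(grid = grid, values = values, units = units, valid = valid),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("gridded_field [%s]: %d x %d, %d valid cells, range %.4g..%.4g\n",
              x$units, x$grid$nlat, x$grid$nlon, sum(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Area-weighted regrid to a coarser nesting grid
#'
#' Aggregates an intensive field (per-m^2 or per-km^2 quantity) to a coarser
#' grid whose resolution is an integer multiple of the source resolution, by
#' the area-weighted mean of the valid source cells inside each target cell.
#' A target cell is invalid only when every contributing source cell is
#' invalid. No interpolation is performed; non-nesting grids are rejected.
#'
#' @param field a [gridded_field()].
#' @param target a coarser [geo_grid()] into which the source nests exactly.
#' @return A [gridded_field()] on `target`.
#' @export
regrid_mean <- function(field, target) {
  stopifnot(inherits(field, "gridded_field"))
  check_grid(target)
  src <- field$grid
  k <- target$resolution / src$resolution
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("grids do not nest: target resolution must be an integer multiple of the source resolution")
  k <- as.integer(round(k))
  a <- cell_areas(src)$area
  w <- a * field$valid
  v <- field$values
  v[!field$valid] <- 0
  # block-sum by k x k tiles
  block <- function(m) {
    m1 <- rowsum(m, rep(seq_len(target$nlat), each = k))
    t(rowsum(t(m1), rep(seq_len(target$nlon), each = k)))
  }
  wsum <- block(w)
  vsum <- block(v * w)
  out <- vsum / wsum
  valid <- wsum > 0
  out[!valid] <- NA_real_
  gridded_field(target, out, field$units, valid)
}

#' Log z-score transform for visualization
#'
#' Returns the z-score of `log(value + eps)` over valid cells, with
#' `eps = min(positive valid value) * 1e-3` so zeros stay finite. The SD is
#' the population SD over valid cells. If the logged values have zero
#' spread the output is 0 everywhere (guard for constant fields). Intended
#' only for display of heavy-tailed fields such as fishing intensity; the
#' quartile analysis always uses raw values.
#'
#' @param field a non-negative [gridded_field()].
#' @return A [gridded_field()] with units `"z(log)"`.
#' @export
log_z <- function(field) {
  stopifnot(inherits(field, "gridded_field"))
  if (!any(field$valid)) stop("log_z: field has no valid cells")
  v <- field$values[field$valid]
  if (any(v < 0)) stop("log_z requires non-negative values")
  pos <- v[v > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1
  lv <- log(v + eps)
  mu <- mean(lv)
  sdv <- sqrt(mean((lv - mu)^2))  # population SD
  z <- if (sdv > 0) (lv - mu) / sdv else rep(0, length(lv))
  out <- field$values
  out[] <- NA_real_
  out[field$valid] <- z
  gridded_field(field$grid, out, "z(log)", field$valid)
}

#' Global integral of an export field
#'
#' Integrates a POC export field (mg C m^-2 day^-1) over the valid domain to
#' a global annual total in Gt C yr^-1:
#' \deqn{\sum_{\mathrm{valid}} E \cdot A_{m^2} \cdot 365 / 10^{18}.}
#'
#' @param export a [gridded_field()] with units `"mg C m-2 day-1"`.
#' @param areas matching [cell_areas()] (km^2).
#' @param domain optional logical matrix restricting the integration domain;
#'   intersected with the field's validity mask.
#' @return Total export in Gt C yr^-1.
#' @export
global_integral <- function(export, areas, domain = NULL) {
  stopifnot(inherits(export, "gridded_field"), inherits(areas, "cell_areas"))
  if (export$units != "mg C m-2 day-1")
    stop(sprintf("global_integral expects units 'mg C m-2 day-1', got '%s'",
                 export$units))
  if (!same_grid(export$grid, areas$grid))
    stop("export field and cell areas are on different grids")
  m <- export$valid
  if (!is.null(domain)) m <- m & domain
  sum(export$values[m] * areas$area[m] * 1e6 * 365) / 1e18
}

#' Read / write a gridded field as a CSV grid dump
#'
#' The CSV dialect has columns `lat_center`, `lon_center`, `value`; missing
#' (invalid) cells are rows with an empty `value` or are simply absent. The
#' grid is reconstructed from the cell centers, which must lie on a uniform
#' global grid.
#'
#' @param path file path.
#' @param units units string for the reconstructed field.
#' @return [read_field_csv()] returns a [gridded_field()];
#'   [write_field_csv()] returns `path` invisibly.
#' @export
read_field_csv <- function(path, units) {
  d <- utils::read.csv(path)
  need <- c("lat_center", "lon_center", "value")
  if (!all(need %in% names(d)))
    stop("CSV grid dump must have columns lat_center, lon_center, value")
  res <- stats::median(diff(sort(unique(d$lat_center))))
  grid <- geo_grid(res)
  i <- match(round(d$lat_center, 6), round(grid$lat_centers, 6))
  j <- match(round(d$lon_center, 6), round(grid$lon_centers, 6))
  if (anyNA(i) || anyNA(j))
    stop("cell centers do not lie on a uniform global grid")
  vals <- matrix(NA_real_, grid$nlat, grid$nlon)
  vals[cbind(i, j)] <- d$value
  gridded_field(grid, vals, units, !is.na(vals))
}

#' @rdname read_field_csv
#' @param field a [gridded_field()] to write.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  g <- field$grid
  d <- data.frame(
    lat_center = rep(g$lat_centers, times = g$nlon),
    lon_center = rep(g$lon_centers, each = g$nlat),
    value = as.vector(ifelse(field$valid, field$values, NA))
  )
  d <- d[!is.na(d$value), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Quick-look plot of a gridded field
#'
#' Minimal `image()`-based preview (longitude on x, latitude on y); invalid
#' cells are blank. For display of fishing intensity pass the field through
#' [log_z()] first.
#'
#' @param x a [gridded_field()].
#' @param ... passed to [graphics::image()].
#' @export
plot.gridded_field <- function(x, ...) {
  z <- ifelse(x$valid, x$values, NA)
  graphics::image(x$grid$lon_centers, x$grid$lat_centers, t(z),
                  xlab = "longitude", ylab = "latitude",
                  main = x$units, ...)
  invisible(x)
}
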