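#' Regular longitude-latitude grid specification
#'
#' Defines a regular lon-lat grid with cell-center registration: cell
#' `[row, col]` (1-based; row indexes latitude, col indexes longitude) has its
#' center at `(lon0 + (col-1)*dlon, lat0 + (row-1)*dlat)`. All gridded fields
#' in the package are `nlat x nlon` matrices in this convention.
#'
#' @param lon0,lat0 Center of cell `[1, 1]`, decimal degrees (WGS-84).
#' @param dlon,dlat Cell size in degrees; must be positive.
#' @param nlon,nlat Number of columns (longitudes) / rows (latitudes); >= 8.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon0, lat0, dlon, dlat, nlon, nlat) {
  if (dlon <= 0 || dlat <= 0) stop("dlon and dlat must be positive")
  if (nlon < 8 || nlat < 8) stop("nlon and nlat must be >= 8")
  structure(list(lon0 = lon0, lat0 = lat0, dlon = dlon, dlat = dlat,
                 nlon = as.integer(nlon), nlat = as.integer(nlat)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, dlon=%g dlat=%g, origin (%g, %g)\n",
              x$nlat, x$nlon, x$dlon, x$dlat, x$lon0, x$lat0))
  invisible(x)
}

#' Cell-center coordinate vectors
#' @param grid A `grid_spec`.
#' @return Numeric vector of cell-center longitudes / latitudes.
#' @export
grid_lons <- function(grid) grid$lon0 + (seq_len(grid$nlon) - 1) * grid$dlon

#' @rdname grid_lons
#' @export
grid_lats <- function(grid) grid$lat0 + (seq_len(grid$nlat) - 1) * grid$dlat

#' Map geographic positions to grid cells
#'
#' A point belongs to the cell whose center is nearest, i.e. cells are
#' rectangles of size `dlon x dlat` around each center. Points outside the
#' grid's outer cell edges get `NA` indices.
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Numeric vectors of equal length.
#' @return A list with integer vectors `row`, `col` (`NA` = outside grid).
#' @export
ll_to_cell <- function(grid, lon, lat) {
  col <- as.integer(round((lon - grid$lon0) / grid$dlon)) + 1L
  row <- as.integer(round((lat - grid$lat0) / grid$dlat)) + 1L
  bad <- col < 1L | col > grid$nlon | row < 1L | row > grid$nlat
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees; vectorized.
#' @param radius_km Earth radius, default 6371 km.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Spherical cell areas for a regular lon-lat grid
#'
#' Cell area by the spherical quadrilateral formula
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))` with `phi1, phi2` the cell's
#' southern/northern edge latitudes.
#'
#' @param grid A `grid_spec`.
#' @param radius_km Earth radius in km.
#' @return `nlat x nlon` matrix of areas in km^2 (constant along rows).
#' @export
cell_area_km2 <- function(grid, radius_km = 6371) {
  to_rad <- pi / 180
  lats <- grid_lats(grid)
  phi1 <- (lats - grid$dlat / 2) * to_rad
  phi2 <- (lats + grid$dlat / 2) * to_rad
  row_area <- radius_km^2 * (grid$dlon * to_rad) * (sin(phi2) - sin(phi1))
  matrix(row_area, nrow = grid$nlat, ncol = grid$nlon)
}

# derive a reproducible 32-bit sub-seed from a master seed and a stream label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 1103 + 17) %% 2147483647)
}
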