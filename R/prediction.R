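## Suitability surfaces and core-habitat maps: weekly replicate-averaged
## predictions, shelf/basin mismatch blending, seasonal averaging with
## warm/cold year filters, accessibility cropping, and quantile core
## thresholds with spherical cell areas.

#' Warm and cold year classifications used for composite surfaces
#' @return Named list with integer vectors `warm` and `cold`.
#' @export
default_year_classes <- function() {
  list(warm = c(1993L, 1998L, 2001:2005, 2014:2016, 2018L),
       cold = c(1992L, 1994:1995, 1997L, 1999L, 2007:2010, 2012:2013))
}

new_surface <- function(grid, values, provenance = list()) {
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("suitability_surface: %d x %d, %d defined cells\n",
              x$grid$nlat, x$grid$nlon, sum(!is.na(x$values))))
  invisible(x)
}

## covariate table for every cell of one weekly slice
weekly_cell_table <- function(env, year, week) {
  g <- env$grid
  d <- data.frame(bathymetry = as.vector(env$bathymetry))
  for (v in ENV_WEEKLY_VARS) d[[v]] <- as.vector(env_field(env, v, year, week))
  d$phl_avg <- as.vector(env$phl_avg[, , year_index(env, year)])
  d
}

#' Predict a weekly suitability surface from an ensemble
#'
#' Assembles the weekly covariate vector for every grid cell, lets each
#' replicate model predict a probability of occurrence, and averages the
#' replicates. Cells of the other habitat are masked out (the shelf model
#' predicts shelf cells, the basin model basin cells); mismatch cells are
#' included for both habitats so they can be blended downstream.
#'
#' @param ensemble A `model_ensemble`.
#' @param env An `env_archive`.
#' @param year,week Weekly slice to predict.
#' @return A `suitability_surface`.
#' @export
predict_weekly <- function(ensemble, env, year, week) {
  g <- env$grid
  d <- weekly_cell_table(env, year, week)
  keep <- as.vector(env$habitat == ensemble$habitat | env$mismatch)
  vals <- rep(NA_real_, nrow(d))
  vals[keep] <- predict(ensemble, d[keep, , drop = FALSE])
  new_surface(g, matrix(vals, g$nlat, g$nlon),
              list(scope = ensemble$scope, habitat = ensemble$habitat,
                   year = year, week = week))
}

#' Blend shelf and basin surfaces across the mismatch zone
#'
#' Mismatch cells get the mean of the shelf and basin predictions; all other
#' cells take their governing model's value.
#'
#' @param shelf,basin `suitability_surface` objects on the same grid.
#' @param mismatch Logical matrix of mismatch cells.
#' @return A combined `suitability_surface`.
#' @export
blend_mismatch <- function(shelf, basin, mismatch) {
  v <- shelf$values
  take_basin <- is.na(v) & !is.na(basin$values)
  v[take_basin] <- basin$values[take_basin]
  both <- mismatch & !is.na(shelf$values) & !is.na(basin$values)
  v[both] <- (shelf$values[both] + basin$values[both]) / 2
  new_surface(shelf$grid, v, list(blended = TRUE))
}

#' Average suitability surfaces, optionally filtering by year class
#'
#' Unweighted cellwise mean over the surfaces passing the filter. `"warm"`
#' and `"cold"` select surfaces whose provenance year is in the respective
#' list (defaults from [default_year_classes()]).
#'
#' @param surfaces List of `suitability_surface` objects on one grid.
#' @param years `"all"`, `"warm"`, `"cold"`, or an integer vector of years.
#' @param year_classes Warm/cold year lists.
#' @return A `suitability_surface` (mean over selected surfaces).
#' @export
average_surfaces <- function(surfaces, years = "all",
                             year_classes = default_year_classes()) {
  if (is.character(years) && length(years) == 1) {
    sel_years <- switch(years,
      all = NULL, warm = year_classes$warm, cold = year_classes$cold,
      stop("unknown year filter: ", years))
  } else sel_years <- as.integer(years)
  if (!is.null(sel_years))
    surfaces <- Filter(function(s) s$provenance$year %in% sel_years, surfaces)
  if (length(surfaces) == 0) stop("no surfaces pass the year filter")
  arr <- vapply(surfaces, function(s) s$values,
                matrix(0, surfaces[[1]]$grid$nlat, surfaces[[1]]$grid$nlon))
  new_surface(surfaces[[1]]$grid,
              apply(arr, c(1, 2), mean),
              list(n_surfaces = length(surfaces), filter = years))
}

#' Crop a surface to an accessibility circle
#'
#' Sets cells whose center lies farther than `radius_km` (haversine) from
#' `center` to missing. The default radius mirrors the region reachable by a
#' central-place forager from the rookery islands.
#'
#' @param surface A `suitability_surface`.
#' @param center `c(lon, lat)` of the circle center.
#' @param radius_km Radius in km (default 375).
#' @return The cropped `suitability_surface`.
#' @export
accessibility_crop <- function(surface, center, radius_km = 375) {
  g <- surface$grid
  lon <- matrix(grid_lons(g), g$nlat, g$nlon, byrow = TRUE)
  lat <- matrix(grid_lats(g), g$nlat, g$nlon)
  d <- haversine_km(lon, lat, center[1], center[2])
  v <- surface$values
  v[d > radius_km] <- NA_real_
  new_surface(g, v, c(surface$provenance,
                      list(crop_center = center, crop_radius_km = radius_km)))
}

#' Core-habitat map from a hindcast-mean surface
#'
#' The threshold is the `q` quantile (linear interpolation between order
#' statistics, R type 7) of the surface's defined cells; a cell is core iff
#' its value is greater than or equal to the threshold, so a continuous
#' surface yields ~`(1-q)*100`% core cells. Area is the sum of spherical
#' cell areas over core cells.
#'
#' @param surface A (cropped) hindcast-mean `suitability_surface`.
#' @param q Quantile defining "top (1-q)" core habitat (default 0.75).
#' @param tau Optional externally supplied threshold (e.g. a hindcast
#'   threshold applied to a projection, or a blended mismatch threshold);
#'   overrides the quantile computation.
#' @return A `core_habitat_map`: `grid`, `tau`, logical `core` matrix (NA
#'   where undefined), `area_km2`.
#' @export
core_threshold <- function(surface, q = 0.75, tau = NULL) {
  v <- surface$values
  if (is.null(tau)) {
    def <- v[!is.na(v)]
    if (length(def) == 0) stop("surface has no defined cells")
    tau <- stats::quantile(def, probs = q, type = 7, names = FALSE)
  }
  core <- v >= tau
  area <- sum(cell_area_km2(surface$grid)[which(core)])
  structure(list(grid = surface$grid, tau = tau, core = core,
                 area_km2 = area, q = q),
            class = "core_habitat_map")
}

#' @export
print.core_habitat_map <- function(x, ...) {
  cat(sprintf("core_habitat_map: tau=%.4f, %d core cells, %.0f km2\n",
              x$tau, sum(x$core, na.rm = TRUE), x$area_km2))
  invisible(x)
}

#' Combined shelf/basin core map with blended mismatch threshold
#'
#' Computes per-model thresholds from the shelf and basin hindcast-mean
#' surfaces, blends the two models across the mismatch zone (mean surface
#' against the mean of the two thresholds), and returns the combined map
#' along with the per-model thresholds.
#'
#' @param shelf,basin Cropped hindcast-mean surfaces of the two models.
#' @param mismatch Logical mismatch matrix.
#' @param q Core quantile (default 0.75).
#' @return List: `map` (`core_habitat_map`), `tau_shelf`, `tau_basin`.
#' @export
core_map_combined <- function(shelf, basin, mismatch, q = 0.75) {
  ts <- core_threshold(shelf, q)$tau
  tb <- core_threshold(basin, q)$tau
  blended <- blend_mismatch(shelf, basin, mismatch)
  v <- blended$values
  core <- matrix(NA, nrow(v), ncol(v))
  sh <- !is.na(shelf$values) & !mismatch
  ba <- !is.na(basin$values) & !mismatch & !sh
  mi <- mismatch & !is.na(v)
  core[sh] <- shelf$values[sh] >= ts
  core[ba] <- basin$values[ba] >= tb
  core[mi] <- v[mi] >= (ts + tb) / 2
  area <- sum(cell_area_km2(shelf$grid)[which(core)])
  list(map = structure(list(grid = shelf$grid, tau = c(shelf = ts, basin = tb),
                            core = core, area_km2 = area, q = q),
                       class = "core_habitat_map"),
       tau_shelf = ts, tau_basin = tb)
}

#' Hindcast suitability pipeline for one ensemble
#'
#' Predicts every (year, Jul-Oct week) weekly surface, and returns the
#' weekly surfaces plus hindcast/warm/cold means.
#'
#' @param ensemble A `model_ensemble`.
#' @param env An `env_archive`.
#' @param years Years to predict (default all archive years).
#' @param weeks Weeks to predict (default the Jul-Oct weeks 27-44).
#' @param year_classes Warm/cold lists for the composites.
#' @return List: `weekly` (list of surfaces), `mean`, `warm`, `cold`.
#' @export
hindcast_surfaces <- function(ensemble, env, years = NULL,
                              weeks = WEEKS_JUL_OCT,
                              year_classes = default_year_classes()) {
  years <- if (is.null(years)) env$years else years
  weekly <- list()
  for (yr in years) for (wk in weeks)
    weekly[[paste0(yr, "_", wk)]] <- predict_weekly(ensemble, env, yr, wk)
  warm <- intersect(years, year_classes$warm)
  cold <- intersect(years, year_classes$cold)
  list(weekly = weekly,
       mean = average_surfaces(weekly, "all"),
       warm = if (length(warm)) average_surfaces(weekly, warm) else NULL,
       cold = if (length(cold)) average_surfaces(weekly, cold) else NULL)
}

#' Write / read a surface as CSV plus JSON sidecar
#' @param surface A `suitability_surface`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path` invisibly; the reader returns a `suitability_surface`.
#' @export
write_surface <- function(surface, path) {
  g <- surface$grid
  d <- data.table::data.table(
    lon = rep(grid_lons(g), each = g$nlat),
    lat = rep(grid_lats(g), g$nlon),
    value = as.vector(surface$values))
  data.table::fwrite(d, path)
  jsonlite::write_json(list(grid = unclass(g), provenance = surface$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- do.call(grid_spec, as.list(hdr$grid))
  d <- data.table::fread(path)
  v <- matrix(NA_real_, g$nlat, g$nlon)
  cell <- ll_to_cell(g, d$lon, d$lat)
  v[cbind(cell$row, cell$col)] <- d$value
  new_surface(g, v, as.list(hdr$provenance))
}
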