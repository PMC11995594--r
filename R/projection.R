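## Climatological bias correction of projected archives, projected
## suitability, and core-habitat change metrics.

#' Bias-correct a projected archive against a hindcast
#'
#' For every variable, cell and week-of-year, the offset is the hindcast
#' climatology minus the forecast climatology over the shared historical
#' window; the offset is added to the forecast for all years (the classic
#' delta-change correction). Biomass variables are floored at zero after
#' correction (the number of floored values is recorded in attribute
#' `n_floored`), and the yearly Apr-Jul phytoplankton mean is recomputed
#' from the corrected weekly fields.
#'
#' @param forecast,hindcast `env_archive` objects on the same grid and
#'   weekly calendar.
#' @param window_years Years of the shared historical window (must be
#'   present in both archives).
#' @param floor_biomass Floor corrected biomass at zero (default `TRUE`).
#'   Disabling gives the raw additive correction, for which the corrected
#'   historical climatology equals the hindcast climatology exactly.
#' @return The corrected forecast `env_archive`.
#' @export
bias_correct <- function(forecast, hindcast, window_years,
                         floor_biomass = TRUE) {
  if (!identical(unclass(forecast$grid), unclass(hindcast$grid)))
    stop("forecast and hindcast grids differ")
  if (!identical(forecast$weeks, hindcast$weeks))
    stop("weekly calendars differ")
  if (length(window_years) == 0) stop("historical window is empty")
  fi <- year_index(forecast, window_years)
  hi <- year_index(hindcast, window_years)
  out <- forecast
  n_floored <- 0L
  for (v in ENV_WEEKLY_VARS) {
    clim_h <- apply(hindcast$weekly[[v]][, , , hi, drop = FALSE], c(1, 2, 3), mean)
    clim_f <- apply(forecast$weekly[[v]][, , , fi, drop = FALSE], c(1, 2, 3), mean)
    offset <- clim_h - clim_f              # [lat, lon, week]
    corrected <- sweep(forecast$weekly[[v]], c(1, 2, 3), offset, "+")
    if (v %in% ENV_BIOMASS_VARS && floor_biomass) {
      n_floored <- n_floored + sum(corrected < 0)
      corrected <- pmax(corrected, 0)
    }
    out$weekly[[v]] <- corrected
  }
  aj <- WEEKS_APR_JUL[WEEKS_APR_JUL <= length(out$weeks)]
  for (yi in seq_along(out$years))
    out$phl_avg[, , yi] <- apply(out$weekly$phl[, , aj, yi, drop = FALSE],
                                 c(1, 2), mean)
  attr(out, "n_floored") <- n_floored
  out
}

#' Project mean suitability over future years
#'
#' Applies the hindcast prediction machinery to a (bias-corrected) projected
#' archive: weekly surfaces for the Jul-Oct weeks of the given years,
#' averaged into a single projection-mean surface.
#'
#' @param ensemble A `model_ensemble`.
#' @param archive A corrected `env_archive`.
#' @param years Projection years.
#' @param weeks Weeks (default Jul-Oct, 27-44).
#' @return A `suitability_surface` (projection mean).
#' @export
project_suitability <- function(ensemble, archive, years,
                                weeks = WEEKS_JUL_OCT) {
  hs <- hindcast_surfaces(ensemble, archive, years = years, weeks = weeks)
  hs$mean
}

#' Suitability-weighted center of gravity of core habitat
#'
#' `COG = sum(w_i * x_i) / sum(w_i)` over core cells, with `w_i` the cell's
#' suitability.
#'
#' @param surface A `suitability_surface`.
#' @param core Logical core matrix (from a `core_habitat_map`).
#' @return `c(lon, lat)`.
#' @export
center_of_gravity <- function(surface, core) {
  g <- surface$grid
  sel <- which(!is.na(core) & core & !is.na(surface$values))
  if (length(sel) == 0) stop("no core cells with defined suitability")
  w <- surface$values[sel]
  lon <- matrix(grid_lons(g), g$nlat, g$nlon, byrow = TRUE)[sel]
  lat <- matrix(grid_lats(g), g$nlat, g$nlon)[sel]
  c(lon = sum(w * lon) / sum(w), lat = sum(w * lat) / sum(w))
}

#' Core-habitat change metrics between hindcast and projection
#'
#' Three metrics over core habitat: mean suitability, total area (spherical
#' cell areas), and the distance from the rookery to the suitability-weighted
#' center of gravity. The projection reuses the hindcast core threshold
#' (applied to the projected mean surface) per the pipeline's convention.
#'
#' @param hind_surface Hindcast-mean `suitability_surface` (cropped).
#' @param proj_surface Projected-mean `suitability_surface` (cropped).
#' @param hind_core A `core_habitat_map` from the hindcast.
#' @param rookery `c(lon, lat)` of the rookery.
#' @return A `change_metrics` data.frame: one row per metric with
#'   `hindcast`, `projected`, `delta`, `delta_pct`.
#' @export
change_metrics <- function(hind_surface, proj_surface, hind_core, rookery) {
  proj_core <- core_threshold(proj_surface, q = hind_core$q,
                              tau = if (length(hind_core$tau) == 1)
                                hind_core$tau else mean(hind_core$tau))
  m_one <- function(surface, core_map) {
    sel <- !is.na(core_map$core) & core_map$core & !is.na(surface$values)
    cog <- center_of_gravity(surface, core_map$core)
    c(mean_suitability = mean(surface$values[sel]),
      area_km2 = core_map$area_km2,
      cog_lon = cog[["lon"]], cog_lat = cog[["lat"]],
      dist_rookery_km = haversine_km(cog[["lon"]], cog[["lat"]],
                                     rookery[1], rookery[2]))
  }
  h <- m_one(hind_surface, hind_core)
  p <- m_one(proj_surface, proj_core)
  metrics <- c("mean_suitability", "area_km2", "dist_rookery_km")
  out <- data.frame(metric = metrics, hindcast = h[metrics],
                    projected = p[metrics])
  out$delta <- out$projected - out$hindcast
  out$delta_pct <- 100 * out$delta / out$hindcast
  attr(out, "cog") <- list(hindcast = h[c("cog_lon", "cog_lat")],
                           projected = p[c("cog_lon", "cog_lat")])
  class(out) <- c("change_metrics", class(out))
  out
}
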