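## Telemetry preprocessing: trip-end trimming, grid-cell and habitat
## assignment with mismatch-zone removal, and nearest-weekly-bin covariate
## extraction.

#' Trim the start and end of each foraging trip
#'
#' Removes records within `hours` of each trip's first and last timestamp
#' (transit to/from the rookery is not foraging habitat). Trips whose total
#' duration is not greater than `2 * hours` are dropped entirely; their ids
#' are recorded in the `"dropped_short"` attribute.
#'
#' @param trips A `trip_set` (or any data.frame with `trip_id`, `timestamp`).
#' @param hours Hours to trim from each end (default 12; 0 = identity).
#' @return The trimmed table, with attribute `dropped_short`.
#' @export
trim_trip_ends <- function(trips, hours = 12) {
  d <- data.table::as.data.table(trips)
  rng <- d[, list(t0 = min(timestamp), t1 = max(timestamp)), by = "trip_id"]
  rng$dur_h <- as.numeric(difftime(rng$t1, rng$t0, units = "hours"))
  short <- rng$trip_id[rng$dur_h <= 2 * hours]
  d <- merge(d, rng[, c("trip_id", "t0", "t1")], by = "trip_id", sort = FALSE)
  keep <- !(d$trip_id %in% short) &
    d$timestamp >= d$t0 + 3600 * hours & d$timestamp <= d$t1 - 3600 * hours
  out <- d[keep, !c("t0", "t1"), with = FALSE]
  data.table::setattr(out, "dropped_short", short)
  out
}

#' Assign trip records to grid cells and habitats
#'
#' Maps each record to its containing cell, assigns shelf/basin habitat from
#' the archive's habitat mask, and removes records that fall outside the grid
#' or in bathymetric-mismatch cells (where the model bathymetry disagrees
#' with the true shelf). Removal counts are kept as attributes
#' `n_outside` and `n_mismatch`.
#'
#' @param trips A (trimmed) trip table.
#' @param env An `env_archive`.
#' @return data.table of located points: trip/animal identifiers, `timestamp`,
#'   `lon`, `lat`, `row`, `col`, `date`, `year`, `habitat`.
#' @export
assign_points <- function(trips, env) {
  d <- data.table::as.data.table(trips)
  cell <- ll_to_cell(env$grid, d$lon, d$lat)
  d$row <- cell$row; d$col <- cell$col
  outside <- is.na(d$row)
  if (all(outside) && nrow(d) > 0) warning("all records fall outside the grid")
  d <- d[!outside]
  mism <- env$mismatch[cbind(d$row, d$col)]
  n_mism <- sum(mism)
  d <- d[!mism]
  d$habitat <- env$habitat[cbind(d$row, d$col)]
  d$date <- as.Date(d$timestamp, tz = "UTC")
  d$year <- as.integer(format(d$date, "%Y"))
  data.table::setattr(d, "n_outside", sum(outside))
  data.table::setattr(d, "n_mismatch", n_mism)
  d
}

## nearest weekly bin for a vector of dates (ties -> earlier bin)
nearest_week_bin <- function(date, weeks_per_year = 52L) {
  weeks_per_year <- as.integer(weeks_per_year)
  yr <- as.integer(format(date, "%Y"))
  wk <- week_of_date(date)
  best_wk <- wk
  best_d <- abs(as.numeric(date - week_center_date(yr, wk)))
  for (off in c(-1L, 1L)) {
    cand <- pmin(pmax(wk + off, 1L), weeks_per_year)
    dd <- abs(as.numeric(date - week_center_date(yr, cand)))
    better <- dd < best_d | (dd == best_d & cand < best_wk)
    best_wk[better] <- cand[better]
    best_d[better] <- dd[better]
  }
  best_wk
}

#' Extract environmental covariates at located points
#'
#' For each point, weekly variables are taken from the weekly bin whose
#' center date is nearest the point's UTC date (ties broken toward the
#' earlier bin), bathymetry from the static field, and the Apr-Jul mean
#' phytoplankton from the point's year.
#'
#' @param points Output of [assign_points()].
#' @param env An `env_archive`.
#' @return `points` with covariate columns appended, plus `week` (the bin
#'   used).
#' @export
extract_covariates <- function(points, env) {
  d <- data.table::as.data.table(points)
  if (nrow(d) == 0) return(d)
  yi <- match(d$year, env$years)
  if (anyNA(yi)) stop("missing weekly bin: year ",
                      paste(unique(d$year[is.na(yi)]), collapse = ","),
                      " not in archive")
  wk <- nearest_week_bin(d$date, length(env$weeks))
  d$week <- wk
  d$bathymetry <- env$bathymetry[cbind(d$row, d$col)]
  for (v in ENV_WEEKLY_VARS)
    d[[v]] <- env$weekly[[v]][cbind(d$row, d$col, wk, yi)]
  d$phl_avg <- env$phl_avg[cbind(d$row, d$col, yi)]
  d
}

#' Majority habitat of a trip
#'
#' @param habitat Character vector of per-point habitats for one trip.
#' @return `"shelf"` or `"basin"` if that habitat holds more than half the
#'   points, else `"mixed"` (used for diagnostics only; modelling splits
#'   points by their own habitat).
#' @export
majority_habitat <- function(habitat) {
  f <- mean(habitat == "shelf")
  if (f > 0.5) "shelf" else if (f < 0.5) "basin" else "mixed"
}
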