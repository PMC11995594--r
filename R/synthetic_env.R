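## Synthetic environmental archives emulating a weekly-averaged, regridded
## shelf-sea ocean model (static bathymetry with a shelf/basin gradient,
## weekly physical and depth-integrated biological fields, optional mid-shelf
## cold pool), plus projected archives with configurable bias and drift, and
## a coarse fishery-catch grid.

default_noise_sd <- function() {
  c(temp_bottom = 0.6, temp_surface = 0.6, phl = 40, ncao_ncas = 25, eup = 20)
}

## Shelf->basin bathymetry: depth increases monotonically from ~20 m at the
## eastern edge to ~3000 m at the western edge through a sigmoidal shelf
## break, with a small latitudinal ripple that preserves monotonicity.
synth_bathymetry <- function(grid) {
  frac <- (grid$nlon - seq_len(grid$nlon)) / (grid$nlon - 1)  # 1 at west edge
  s <- stats::plogis((frac - 0.45) * 10)
  g <- (s - min(s)) / (max(s) - min(s))
  depth_col <- 20 * (3000 / 20)^g
  ripple <- 1 + 0.04 * sin(2 * pi * (seq_len(grid$nlat) - 1) / (grid$nlat - 1))
  outer(ripple, depth_col)
}

## deterministic weekly base fields (no noise), as functions of depth,
## latitude and week-of-year
synth_base_field <- function(var, bathy, grid, week, cold_pool_bump = NULL) {
  lats <- grid_lats(grid)
  latw <- (max(lats) - lats) / (max(lats) - min(lats))  # 1 in the south
  latm <- matrix(latw, grid$nlat, grid$nlon)
  f <- switch(var,
    temp_surface = 7 + 4 * cos(2 * pi * (week - 33) / 52) + 2.5 * latm,
    temp_bottom = 1.0 + 4.5 * (1 - exp(-bathy / 400)) +
      0.8 * cos(2 * pi * (week - 36) / 52),
    ## depth-integrated biomass peaks along the shelf break (a "green belt"
    ## of enhanced production), not monotonically with depth
    phl = (60 + 300 * exp(-(bathy - 100)^2 / (2 * 85^2))) *
      (1 + 0.35 * cos(2 * pi * (week - 22) / 52)),
    ncao_ncas = (40 + 200 * exp(-(bathy - 90)^2 / (2 * 110^2))) *
      (1 + 0.25 * cos(2 * pi * (week - 30) / 52)),
    eup = (30 + 160 * exp(-(bathy - 100)^2 / (2 * 110^2))) *
      (1 + 0.2 * cos(2 * pi * (week - 32) / 52)),
    stop("unknown variable: ", var))
  if (var == "temp_bottom" && !is.null(cold_pool_bump)) f <- f - cold_pool_bump
  f
}

## mid-shelf cold-pool anomaly (Gaussian bump subtracted from bottom temp)
cold_pool_bump <- function(grid, bathy, amplitude = 4) {
  r0 <- round(grid$nlat * 0.72)        # northern mid-shelf, as left by winter ice
  c0 <- which.min(abs(bathy[r0, ] - 80))  # mid-shelf column
  rad <- max(3, grid$nlat / 8)
  rr <- outer((seq_len(grid$nlat) - r0)^2, (seq_len(grid$nlon) - c0)^2, "+")
  amplitude * exp(-rr / (2 * rad^2))
}

## row/col Gaussian smoothing operators with edge mass renormalization;
## smoothing a white-noise matrix with these yields spatially autocorrelated
## noise with correlation length ~ smooth_cells
smoothing_operator <- function(n, smooth_cells) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * smooth_cells^2))
  k / rowSums(k)
}

smooth_noise <- function(nlat, nlon, k_lat, k_lon, sd_target) {
  z <- k_lat %*% matrix(stats::rnorm(nlat * nlon), nlat, nlon) %*% t(k_lon)
  if (sd_target == 0) return(matrix(0, nlat, nlon))
  z * (sd_target / stats::sd(z))
}

## core generator shared by hindcast and projected archives
generate_archive <- function(grid, years, weeks_per_year, cold_pool, noise_sd,
                             smooth_cells, mismatch_scale, seed,
                             bias = NULL, drift = NULL, drift_origin = NULL) {
  if (length(years) == 0) stop("years must be nonempty")
  years <- as.integer(sort(years))
  weeks <- seq_len(weeks_per_year)
  bathy <- synth_bathymetry(grid)
  bump <- if (cold_pool) cold_pool_bump(grid, bathy) else NULL
  k_lat <- smoothing_operator(grid$nlat, smooth_cells)
  k_lon <- smoothing_operator(grid$nlon, smooth_cells)
  nsd <- default_noise_sd()
  if (!is.null(noise_sd)) nsd[names(noise_sd)] <- noise_sd
  weekly <- lapply(stats::setNames(ENV_WEEKLY_VARS, ENV_WEEKLY_VARS), function(v)
    array(NA_real_, c(grid$nlat, grid$nlon, weeks_per_year, length(years))))
  for (yi in seq_along(years)) {
    yr <- years[yi]
    set.seed(derive_seed(seed, paste0("envyear", yr)))
    for (v in ENV_WEEKLY_VARS) {
      off <- 0
      if (!is.null(bias) && !is.na(bias[v])) off <- off + bias[[v]]
      if (!is.null(drift) && !is.na(drift[v]))
        off <- off + drift[[v]] * (yr - drift_origin) / 10
      ## biomass fields get per-year regional anomalies (good/poor production
      ## years with coherent spatial pattern) whose pattern evolves between
      ## the spring bloom and summer, on top of weekly noise
      if (v %in% ENV_BIOMASS_VARS) {
        anom_spring <- smooth_noise(grid$nlat, grid$nlon, k_lat, k_lon, 2 * nsd[[v]])
        anom_summer <- 0.5 * anom_spring +
          sqrt(0.75) * smooth_noise(grid$nlat, grid$nlon, k_lat, k_lon, 2 * nsd[[v]])
      } else anom_spring <- anom_summer <- 0
      for (w in weeks) {
        anom <- if (w <= 26) anom_spring else anom_summer
        f <- synth_base_field(v, bathy, grid, w, bump) + off + anom +
          smooth_noise(grid$nlat, grid$nlon, k_lat, k_lon, nsd[[v]])
        if (v %in% ENV_BIOMASS_VARS) f <- pmax(f, 0)
        weekly[[v]][, , w, yi] <- f
      }
    }
  }
  aj <- WEEKS_APR_JUL[WEEKS_APR_JUL <= weeks_per_year]
  phl_avg <- array(NA_real_, c(grid$nlat, grid$nlon, length(years)))
  for (yi in seq_along(years))
    phl_avg[, , yi] <- apply(weekly$phl[, , aj, yi, drop = FALSE], c(1, 2), mean)
  habitat <- ifelse(bathy <= 200, "shelf", "basin")
  mismatch <- bathy > 200 & bathy * mismatch_scale <= 200
  structure(list(grid = grid, years = years, weeks = weeks, bathymetry = bathy,
                 weekly = weekly, phl_avg = phl_avg, habitat = habitat,
                 mismatch = mismatch, depth_rule = 200,
                 gen = list(weeks_per_year = weeks_per_year,
                            cold_pool = cold_pool,
                            noise_sd = as.list(nsd),
                            smooth_cells = smooth_cells,
                            mismatch_scale = mismatch_scale, seed = seed)),
            class = "env_archive")
}

#' Generate a synthetic environmental archive
#'
#' Builds a gridded hindcast-style archive with a static shelf-to-basin
#' bathymetry gradient (~20 m to ~3000 m through a sigmoidal shelf break at
#' 200 m), weekly bottom/surface temperature and depth-integrated large
#' phytoplankton, large copepod and euphausiid biomass (smooth deterministic
#' base gradients plus kernel-smoothed spatially autocorrelated noise), a
#' yearly Apr-Jul mean phytoplankton field computed exactly from the weekly
#' fields, a shelf/basin habitat mask (depth <= 200 m rule) and a bathymetric
#' mismatch mask (model depth > 200 m but "true" depth <= 200 m, emulated by
#' scaling the model bathymetry by `mismatch_scale`).
#'
#' @param grid A `grid_spec`.
#' @param years Integer vector of simulated years (nonempty).
#' @param weeks_per_year Number of weekly bins (default 52, week 1 = Jan 1).
#' @param cold_pool If `TRUE`, a contiguous mid-shelf patch of bottom water
#'   below 2 degC is imposed (a Gaussian cold anomaly).
#' @param noise_sd Named numeric: standard deviation of the autocorrelated
#'   noise per variable (0 = deterministic base field). Defaults: 0.6 degC for
#'   temperatures, 40/25/20 mg C m-2 for phl/ncao_ncas/eup.
#' @param smooth_cells Gaussian smoothing length of the noise, in cells (>= 3).
#' @param mismatch_scale Multiplier giving the "true" bathymetry used to
#'   derive the mismatch mask.
#' @param seed Integer seed; identical seeds give bit-identical archives.
#' @return An `env_archive`.
#' @export
make_environment <- function(grid, years, weeks_per_year = 52, cold_pool = TRUE,
                             noise_sd = NULL, smooth_cells = 3,
                             mismatch_scale = 0.85, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  generate_archive(grid, years, weeks_per_year, cold_pool, noise_sd,
                   smooth_cells, mismatch_scale, seed)
}

#' Generate a projected archive with known bias and drift
#'
#' Regenerates the synthetic world of `env` (same grid, bathymetry, base
#' fields and noise model) over `historical_years` and `future_years`, adding
#' a constant per-variable offset (`esm_bias`, emulating systematic Earth
#' System Model bias) and a linear trend (`drift`, units per decade, measured
#' from the start of the historical window). Using the same `seed` as `env`
#' reproduces the identical noise for shared years, so with zero bias and
#' drift the historical segment equals the hindcast exactly.
#'
#' @param env The reference `env_archive` whose world is being projected.
#' @param drift Named numeric, units per decade per variable (default 0).
#' @param historical_years,future_years Integer year vectors.
#' @param esm_bias Named numeric constant offset per variable (default 0).
#' @param seed Integer seed for the regenerated noise.
#' @return An `env_archive` spanning `historical_years` and `future_years`.
#' @export
make_projection_archive <- function(env, drift = NULL, historical_years,
                                    future_years, esm_bias = NULL, seed = 1) {
  stopifnot(is_env_archive(env))
  zero <- stats::setNames(rep(0, length(ENV_WEEKLY_VARS)), ENV_WEEKLY_VARS)
  b <- zero; if (!is.null(esm_bias)) b[names(esm_bias)] <- esm_bias
  d <- zero; if (!is.null(drift)) d[names(drift)] <- drift
  g <- env$gen
  generate_archive(env$grid, c(historical_years, future_years),
                   g$weeks_per_year, g$cold_pool, unlist(g$noise_sd),
                   g$smooth_cells, g$mismatch_scale, seed,
                   bias = b, drift = d, drift_origin = min(historical_years))
}

#' Generate a coarse fishery-catch grid
#'
#' Builds a 0.25-degree (by default) catch grid covering the archive extent.
#' Modes: `"uniform"` spreads the total evenly over all coarse cells;
#' `"shelf-weighted"` weights each coarse cell by the fraction of fine shelf
#' cells it contains (so pure-basin cells get zero); `"from-mask"` places the
#' total evenly over the supplied coarse `cells` only (empty mask = all zero).
#'
#' @param env An `env_archive`.
#' @param mode One of `"uniform"`, `"shelf-weighted"`, `"from-mask"`.
#' @param total_t Total catch in tonnes, conserved exactly.
#' @param resolution Coarse cell size in degrees.
#' @param cells For `"from-mask"`: integer matrix/data.frame with columns
#'   `row`, `col` of coarse cells to receive catch.
#' @param seed Unused in the deterministic modes; kept for interface symmetry.
#' @return A `catch_grid`: list(grid = coarse `grid_spec`, catch = matrix).
#' @export
make_catch_grid <- function(env, mode = c("uniform", "shelf-weighted", "from-mask"),
                            total_t = 1000, resolution = 0.25, cells = NULL,
                            seed = 1) {
  mode <- match.arg(mode)
  fine <- env$grid
  lon_min <- fine$lon0 - fine$dlon / 2; lat_min <- fine$lat0 - fine$dlat / 2
  lon_max <- fine$lon0 + (fine$nlon - 0.5) * fine$dlon
  lat_max <- fine$lat0 + (fine$nlat - 0.5) * fine$dlat
  nlon <- max(8L, ceiling((lon_max - lon_min) / resolution))
  nlat <- max(8L, ceiling((lat_max - lat_min) / resolution))
  coarse <- grid_spec(lon_min + resolution / 2, lat_min + resolution / 2,
                      resolution, resolution, nlon, nlat)
  w <- matrix(0, nlat, nlon)
  if (mode == "uniform") {
    w[] <- 1
  } else if (mode == "shelf-weighted") {
    fl <- grid_lons(fine); fa <- grid_lats(fine)
    idx <- ll_to_cell(coarse, rep(fl, each = fine$nlat), rep(fa, fine$nlon))
    shelf <- as.vector(env$habitat == "shelf")
    ok <- !is.na(idx$row)
    for (i in which(ok & shelf)) w[idx$row[i], idx$col[i]] <- w[idx$row[i], idx$col[i]] + 1
  } else {
    if (!is.null(cells) && NROW(cells) > 0) {
      cells <- as.data.frame(cells)
      w[cbind(cells$row, cells$col)] <- 1
    }
  }
  tot <- sum(w)
  catch <- if (tot > 0) w * (total_t / tot) else w
  structure(list(grid = coarse, catch = catch), class = "catch_grid")
}

#' Write / read a catch grid as CSV (`lon, lat, catch_t`, cell centers)
#' @param x A `catch_grid`.
#' @param path CSV file path.
#' @return `path` invisibly; `read_catch_grid` returns a `catch_grid`.
#' @export
write_catch_grid <- function(x, path) {
  g <- x$grid
  d <- data.table::data.table(
    lon = rep(grid_lons(g), each = g$nlat),
    lat = rep(grid_lats(g), g$nlon),
    catch_t = as.vector(x$catch))
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_catch_grid
#' @export
read_catch_grid <- function(path) {
  d <- data.table::fread(path)
  lons <- sort(unique(d$lon)); lats <- sort(unique(d$lat))
  g <- grid_spec(lons[1], lats[1], diff(lons)[1], diff(lats)[1],
                 length(lons), length(lats))
  m <- matrix(0, g$nlat, g$nlon)
  m[cbind(match(d$lat, lats), match(d$lon, lons))] <- d$catch_t
  structure(list(grid = g, catch = m), class = "catch_grid")
}
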