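## EnvArchive container + weekly calendar helpers + text serialization.
##
## An env_archive is a list:
##   grid        grid_spec
##   years       integer vector
##   weeks       integer vector (1..weeks_per_year)
##   bathymetry  nlat x nlon matrix, depth in m (>= 0, positive down)
##   weekly      named list of 4-d arrays [lat, lon, week, year]:
##               temp_bottom, temp_surface, phl, ncao_ncas, eup
##   phl_avg     3-d array [lat, lon, year]: Apr-Jul mean large phytoplankton
##   habitat     character matrix "shelf"/"basin" (shelf: depth <= depth_rule)
##   mismatch    logical matrix: model depth > rule but "true" depth <= rule
##   depth_rule  m (default 200)
##   gen         generator parameters (kept so projections can re-derive the
##               same deterministic base fields)

ENV_WEEKLY_VARS <- c("temp_bottom", "temp_surface", "phl", "ncao_ncas", "eup")
ENV_BIOMASS_VARS <- c("phl", "ncao_ncas", "eup")
ENV_UNITS <- c(temp_bottom = "degC", temp_surface = "degC",
               phl = "mg C m-2", ncao_ncas = "mg C m-2", eup = "mg C m-2",
               bathymetry = "m", phl_avg = "mg C m-2")

## weeks used for the Apr-Jul yearly phytoplankton mean and for the Jul-Oct
## prediction season (52-week calendar, week 1 starts Jan 1)
WEEKS_APR_JUL <- 14:30
WEEKS_JUL_OCT <- 27:44

#' Week-of-year of a date (52-week calendar)
#'
#' Week 1 starts Jan 1; weeks are 7 days, with the leftover 1-2 days of the
#' year folded into week 52. This fixed binning mirrors weekly-averaged ocean
#' model archives.
#'
#' @param date A `Date` vector.
#' @return Integer week numbers in 1..52.
#' @export
week_of_date <- function(date) {
  yd <- as.POSIXlt(date)$yday  # 0-based day of year
  pmin(52L, yd %/% 7L + 1L)
}

#' Center date of a weekly bin
#' @param year,week Integer vectors (recycled).
#' @return `Date` vector: day 4 of the 7-day bin.
#' @export
week_center_date <- function(year, week) {
  as.Date(paste0(year, "-01-01")) + (week - 1L) * 7L + 3L
}

is_env_archive <- function(x) inherits(x, "env_archive")

#' @export
print.env_archive <- function(x, ...) {
  cat(sprintf("env_archive: %d x %d grid, years %s, %d weekly variables\n",
              x$grid$nlat, x$grid$nlon,
              paste(range(x$years), collapse = "-"), length(x$weekly)))
  invisible(x)
}

## index of a year within an archive (hard error when absent)
year_index <- function(env, year) {
  i <- match(year, env$years)
  if (anyNA(i)) stop("year(s) ", paste(year[is.na(i)], collapse = ","),
                     " not present in archive")
  i
}

#' Extract one weekly field
#' @param env An `env_archive`.
#' @param var One of `temp_bottom`, `temp_surface`, `phl`, `ncao_ncas`, `eup`.
#' @param year,week Scalar year and week.
#' @return `nlat x nlon` matrix.
#' @export
env_field <- function(env, var, year, week) {
  if (!var %in% names(env$weekly)) stop("unknown weekly variable: ", var)
  if (!week %in% env$weeks) stop("week ", week, " not present in archive")
  env$weekly[[var]][, , week, year_index(env, year)]
}

#' Write / read an environmental archive as plain text
#'
#' The archive is stored as a directory holding a JSON header (grid, years,
#' units) plus long-format CSV tables (one row per cell/week/year value).
#' This is a text stand-in for the NetCDF layout the field normally uses,
#' chosen because no NetCDF interface is available to the package.
#'
#' @param env An `env_archive`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly (`read_env_archive` returns the archive).
#' @export
write_env_archive <- function(env, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(grid = unclass(env$grid), years = env$years, weeks = env$weeks,
              depth_rule = env$depth_rule, units = as.list(ENV_UNITS),
              gen = env$gen)
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  g <- env$grid
  static <- data.table::data.table(
    row = rep(seq_len(g$nlat), g$nlon),
    col = rep(seq_len(g$nlon), each = g$nlat),
    bathymetry = as.vector(env$bathymetry),
    habitat = as.vector(env$habitat),
    mismatch = as.vector(env$mismatch))
  data.table::fwrite(static, file.path(path, "static.csv"))
  wk <- data.table::rbindlist(lapply(names(env$weekly), function(v) {
    a <- env$weekly[[v]]
    data.table::data.table(
      var = v,
      row = rep(seq_len(g$nlat), times = length(a) / g$nlat),
      col = rep(rep(seq_len(g$nlon), each = g$nlat), times = dim(a)[3] * dim(a)[4]),
      week = rep(rep(env$weeks, each = g$nlat * g$nlon), times = dim(a)[4]),
      year = rep(env$years, each = g$nlat * g$nlon * dim(a)[3]),
      value = as.vector(a))
  }))
  data.table::fwrite(wk, file.path(path, "weekly.csv"))
  pa <- data.table::data.table(
    row = rep(seq_len(g$nlat), times = g$nlon * length(env$years)),
    col = rep(rep(seq_len(g$nlon), each = g$nlat), times = length(env$years)),
    year = rep(env$years, each = g$nlat * g$nlon),
    value = as.vector(env$phl_avg))
  data.table::fwrite(pa, file.path(path, "phl_avg.csv"))
  invisible(path)
}

#' @rdname write_env_archive
#' @export
read_env_archive <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  grid <- do.call(grid_spec, as.list(hdr$grid))
  years <- as.integer(hdr$years); weeks <- as.integer(hdr$weeks)
  static <- data.table::fread(file.path(path, "static.csv"))
  nlat <- grid$nlat; nlon <- grid$nlon
  m <- function(v) matrix(v[order(static$col, static$row)], nlat, nlon)
  bathy <- m(static$bathymetry)
  habitat <- matrix(static$habitat[order(static$col, static$row)], nlat, nlon)
  mism <- m(static$mismatch)
  wk <- data.table::fread(file.path(path, "weekly.csv"))
  weekly <- lapply(stats::setNames(ENV_WEEKLY_VARS, ENV_WEEKLY_VARS), function(v) {
    d <- wk[wk$var == v, ]
    a <- array(NA_real_, c(nlat, nlon, length(weeks), length(years)))
    a[cbind(d$row, d$col, d$week, match(d$year, years))] <- d$value
    a
  })
  pa <- data.table::fread(file.path(path, "phl_avg.csv"))
  phl_avg <- array(NA_real_, c(nlat, nlon, length(years)))
  phl_avg[cbind(pa$row, pa$col, match(pa$year, years))] <- pa$value
  structure(list(grid = grid, years = years, weeks = weeks,
                 bathymetry = bathy, weekly = weekly, phl_avg = phl_avg,
                 habitat = habitat, mismatch = mism == TRUE,
                 depth_rule = hdr$depth_rule, gen = hdr$gen),
            class = "env_archive")
}
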