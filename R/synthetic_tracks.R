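## Synthetic central-place foraging trips: hourly positions driven by a
## first-order autoregressive step process, departing from and returning to a
## rookery, with optional habitat selection imposed by weighted resampling of
## candidate steps. With selection strength 0 the generator reduces exactly
## to the null AR(1) model used for pseudo-absence simulation, which is what
## makes the AUC ~ 0.5 null calibration meaningful.

KM_PER_DEG_LAT <- 111.32

#' Habitat-selection specification for the track simulator
#'
#' Ground-truth preference functions used to bias simulated movement, so that
#' downstream models can be tested for recovery of a known signal. Each
#' element of `prefs` is a piecewise-linear function (breakpoints `x`,
#' nonnegative weights `w`) over one environmental variable (`bathymetry` or
#' any weekly variable). The per-step selection weight is
#' `(prod_v pref_v(value))^strength`; `strength = 0` disables selection.
#'
#' @param prefs Named list of `list(x = breakpoints, w = weights >= 0)`.
#' @param strength Nonnegative scalar selection strength.
#' @return A `selection_spec`.
#' @export
selection_spec <- function(prefs = list(), strength = 0) {
  stopifnot(strength >= 0)
  for (p in prefs) {
    stopifnot(is.numeric(p$x), is.numeric(p$w), length(p$x) == length(p$w))
    if (any(!is.finite(p$w)) || any(p$w < 0)) stop("preference weights must be finite and >= 0")
  }
  structure(list(prefs = prefs, strength = strength), class = "selection_spec")
}

## per-cell selection weight field for a given (year, week)
selection_weight_field <- function(env, selection, year, week) {
  g <- env$grid
  w <- matrix(1, g$nlat, g$nlon)
  if (selection$strength == 0 || length(selection$prefs) == 0) return(w)
  for (v in names(selection$prefs)) {
    p <- selection$prefs[[v]]
    val <- if (v == "bathymetry") env$bathymetry else env_field(env, v, year, week)
    w <- w * matrix(stats::approx(p$x, p$w, xout = as.vector(val), rule = 2)$y,
                    g$nlat, g$nlon)
  }
  w^selection$strength
}

#' Default rookery complexes for a synthetic archive
#'
#' Places two rookery complexes on the outer shelf (cell with depth nearest 70 m)
#' at 62% and 42% of the grid's latitude extent, mimicking a pair of breeding
#' islands seaward of the shelf break.
#'
#' @param env An `env_archive`.
#' @return data.frame with columns `complex`, `lon`, `lat`.
#' @export
default_complexes <- function(env) {
  g <- env$grid
  lats <- grid_lats(g); lons <- grid_lons(g)
  place <- function(frac) {
    r <- which.min(abs(lats - (min(lats) + frac * diff(range(lats)))))
    c <- which.min(abs(env$bathymetry[r, ] - 70))
    c(lons[c], lats[r])
  }
  p1 <- place(0.62); p2 <- place(0.42)
  data.frame(complex = c("North", "South"),
             lon = c(p1[1], p2[1]), lat = c(p1[2], p2[2]))
}

#' Simulate central-place foraging trips
#'
#' Hourly step vectors follow a first-order autoregressive process
#' `s_t = phi * s_(t-1) + eps_t` (per lon/lat component, in km converted to
#' degrees at the rookery latitude). At each hour, `n_candidates` candidate
#' steps are drawn and one is resampled with probability proportional to the
#' selection weight at the candidate destination (uniform when
#' `selection$strength == 0`, giving the pure null model). After the free
#' simulation the closure error is removed by subtracting `error / n_steps`
#' from every step, pinning the trip to start and end at the rookery.
#' Trip durations are truncated-normal (mean 6.6 d, sd 2.4 d, minimum 1 d);
#' trips start on random dates in July-September of random archive years.
#'
#' @param env An `env_archive`.
#' @param animals Number of animals.
#' @param trips_per_animal Trips per animal.
#' @param selection A `selection_spec` (default: no selection).
#' @param step_params List: `mean_step_km` (stationary mean hourly step
#'   length, default 4.5), `ar` (AR coefficient, |phi| < 1, default 0.75),
#'   `innovation_sd_km` (overrides the sd implied by `mean_step_km`).
#' @param duration_mean_d,duration_sd_d Trip duration distribution (days).
#' @param complexes data.frame `complex, lon, lat` of rookeries; default
#'   [default_complexes()]. Animals are assigned round-robin.
#' @param n_candidates Candidate steps per hour under selection.
#' @param seed Integer seed; identical seeds give bit-identical trip sets.
#' @return A `trip_set`: data.table with columns `animal_id, complex,
#'   rookery_lon, rookery_lat, trip_id, timestamp (POSIXct UTC), lon, lat`.
#' @export
simulate_tracks <- function(env, animals, trips_per_animal,
                            selection = selection_spec(),
                            step_params = list(mean_step_km = 4.5, ar = 0.75),
                            duration_mean_d = 6.6, duration_sd_d = 2.4,
                            complexes = NULL, n_candidates = 15, seed = 1) {
  stopifnot(is_env_archive(env))
  phi <- step_params$ar %||% 0.75
  if (abs(phi) >= 1) stop("AR coefficient magnitude must be < 1")
  mean_step <- step_params$mean_step_km %||% 4.5
  sigma_km <- mean_step / sqrt(pi / 2)            # stationary component sd
  sd_inn_km <- step_params$innovation_sd_km %||% (sigma_km * sqrt(1 - phi^2))
  sigma_km <- sd_inn_km / sqrt(1 - phi^2)
  if (is.null(complexes)) complexes <- default_complexes(env)
  g <- env$grid
  ok <- !is.na(ll_to_cell(g, complexes$lon, complexes$lat)$row)
  if (any(!ok)) stop("rookery outside grid: ", paste(complexes$complex[!ok], collapse = ","))

  set.seed(derive_seed(seed, "tracks"))
  wcache <- new.env(parent = emptyenv())
  get_wfield <- function(year, week) {
    key <- paste0(year, "_", week)
    if (is.null(wcache[[key]]))
      wcache[[key]] <- selection_weight_field(env, selection, year, week)
    wcache[[key]]
  }
  use_selection <- selection$strength > 0 && length(selection$prefs) > 0
  K <- if (use_selection) n_candidates else 1L

  out <- vector("list", animals * trips_per_animal)
  ti <- 0L
  for (a in seq_len(animals)) {
    cx <- complexes[((a - 1L) %% nrow(complexes)) + 1L, ]
    deg_x <- 1 / (KM_PER_DEG_LAT * cos(cx$lat * pi / 180))
    deg_y <- 1 / KM_PER_DEG_LAT
    for (tr in seq_len(trips_per_animal)) {
      ti <- ti + 1L
      year <- env$years[sample.int(length(env$years), 1L)]
      start_day <- as.Date(paste0(year, "-07-01")) + sample.int(92L, 1L) - 1L
      start <- as.POSIXct(paste0(format(start_day), " 00:00:00"), tz = "UTC") +
        3600 * (sample.int(24L, 1L) - 1L)
      T_h <- round(truncnorm::rtruncnorm(1, a = 24, mean = duration_mean_d * 24,
                                         sd = duration_sd_d * 24))
      steps <- matrix(0, T_h, 2)  # degrees (lon, lat)
      pos <- c(cx$lon, cx$lat)
      s_prev <- stats::rnorm(2, 0, sigma_km)  # km components, stationary init
      tstamps <- start + 3600 * (0:T_h)
      wks <- week_of_date(as.Date(tstamps[-1]))
      for (t in seq_len(T_h)) {
        ## bridge-style pinning: deterministic homing drift spread over the
        ## remaining steps keeps the trip returning to the rookery while the
        ## AR state evolves freely
        hdrift <- (c(cx$lon, cx$lat) - pos) / (T_h - t + 1)
        eps <- matrix(stats::rnorm(2L * K, 0, sd_inn_km), K, 2)
        cand_km <- sweep(eps, 2, phi * s_prev, "+")
        cand_deg <- cbind(cand_km[, 1] * deg_x + hdrift[1],
                          cand_km[, 2] * deg_y + hdrift[2])
        cand_lon <- pos[1] + cand_deg[, 1]
        cand_lat <- pos[2] + cand_deg[, 2]
        cell <- ll_to_cell(g, cand_lon, cand_lat)
        inb <- !is.na(cell$row)
        if (use_selection) {
          wf <- get_wfield(year, wks[t])
          w <- numeric(K)
          w[inb] <- wf[cbind(cell$row[inb], cell$col[inb])]
        } else w <- as.numeric(inb)
        pick <- if (sum(w) > 0) {
          if (K == 1L) 1L else sample.int(K, 1L, prob = w)
        } else { # all candidates out of grid (or zero weight): reflect AR part
          cand_km[1, ] <- -cand_km[1, ]
          cand_deg[1, ] <- c(cand_km[1, 1] * deg_x + hdrift[1],
                             cand_km[1, 2] * deg_y + hdrift[2])
          1L
        }
        s_prev <- cand_km[pick, ]
        steps[t, ] <- cand_deg[pick, ]
        pos <- pos + steps[t, ]
      }
      ## residual closure error after the bridge is one innovation in size;
      ## remove it uniformly so endpoints are exact
      err <- pos - c(cx$lon, cx$lat)
      steps <- sweep(steps, 2, err / T_h)
      lon <- cx$lon + c(0, cumsum(steps[, 1]))
      lat <- cx$lat + c(0, cumsum(steps[, 2]))
      out[[ti]] <- data.table::data.table(
        animal_id = sprintf("A%03d", a), complex = cx$complex,
        rookery_lon = cx$lon, rookery_lat = cx$lat,
        trip_id = sprintf("A%03d_T%02d", a, tr),
        timestamp = tstamps, lon = lon, lat = lat)
    }
  }
  res <- data.table::rbindlist(out)
  class(res) <- c("trip_set", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trip set as CSV (ISO-8601 UTC timestamps)
#' @param trips A `trip_set`.
#' @param path CSV file path.
#' @return `path` invisibly; `read_trip_set` returns a `trip_set`.
#' @export
write_trip_set <- function(trips, path) {
  d <- data.table::as.data.table(trips)
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_trip_set
#' @export
read_trip_set <- function(path) {
  d <- data.table::fread(path)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  class(d) <- c("trip_set", class(d))
  d
}

#' Canonical strong-selection scenario
#'
#' The ground-truth preference used in recovery experiments: selection for
#' the outer-shelf depth band (75-200 m; weight 1 inside, 0.01 outside) and
#' for cold bottom water (weight 1 below -1 degC declining to 0.01 by 2 degC,
#' i.e. selection against bottom temperatures above a few degrees). At
#' `strength = 3` simulated animals concentrate strongly in cold outer-shelf
#' habitat; at `strength = 0` the generator is the pure null model.
#'
#' @param strength Selection strength (default 3).
#' @return A `selection_spec`.
#' @export
depth_band_selection <- function(strength = 3) {
  selection_spec(list(
    bathymetry = list(x = c(0, 60, 75, 200, 260, 4000),
                      w = c(0.01, 0.01, 1, 1, 0.01, 0.01)),
    temp_bottom = list(x = c(-8, -1, 2, 20), w = c(1, 1, 0.01, 0.01))),
    strength = strength)
}
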