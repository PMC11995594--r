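# Synthetic environmental archive and track generator.

test_that("zero-noise archive equals its deterministic base fields", {
  g <- tiny_grid()
  nsd <- stats::setNames(rep(0, 5), cpfhabitat:::ENV_WEEKLY_VARS)
  env <- make_environment(g, 2001, noise_sd = nsd, seed = 5)
  bathy <- cpfhabitat:::synth_bathymetry(g)
  bump <- cpfhabitat:::cold_pool_bump(g, bathy)
  for (v in c("temp_bottom", "phl")) for (w in c(1, 27, 52)) {
    base <- cpfhabitat:::synth_base_field(v, bathy, g, w, bump)
    if (v %in% cpfhabitat:::ENV_BIOMASS_VARS) base <- pmax(base, 0)
    expect_equal(env_field(env, v, 2001, w), base, tolerance = 0)
  }
  # seed is irrelevant when noise is off
  env2 <- make_environment(g, 2001, noise_sd = nsd, seed = 99)
  expect_identical(env$weekly, env2$weekly)
})

test_that("phl_avg is the cellwise Apr-Jul mean of weekly phl", {
  env <- tiny_env()
  for (yi in seq_along(env$years)) {
    oracle <- apply(env$weekly$phl[, , 14:30, yi], c(1, 2), mean)
    expect_equal(env$phl_avg[, , yi], oracle, tolerance = 1e-12)
  }
})

test_that("habitat and mismatch masks follow the 200 m rule exactly", {
  env <- tiny_env()
  n_shelf_brute <- 0L
  for (r in seq_len(env$grid$nlat)) for (c in seq_len(env$grid$nlon))
    if (env$bathymetry[r, c] <= 200) n_shelf_brute <- n_shelf_brute + 1L
  expect_identical(sum(env$habitat == "shelf"), n_shelf_brute)
  expect_identical(env$habitat == "shelf", env$bathymetry <= 200)
  expect_identical(env$mismatch,
                   env$bathymetry > 200 & env$bathymetry * 0.85 <= 200)
  expect_gt(sum(env$mismatch), 0)
})

test_that("bathymetry runs monotonically from shelf (~20 m) to basin (~3000 m)", {
  env <- tiny_env()
  # increasing toward the west edge (decreasing column index), every row
  expect_true(all(apply(env$bathymetry, 1, function(r) all(diff(r) <= 0))))
  expect_lt(min(env$bathymetry), 30)
  expect_gt(max(env$bathymetry), 2500)
})

test_that("cold pool forms a contiguous mid-shelf patch below 2 degC", {
  env <- tiny_env()
  g <- env$grid
  bathy <- env$bathymetry
  r0 <- round(g$nlat * 0.72)
  c0 <- which.min(abs(bathy[r0, ] - 80))
  patch <- env_field(env, "temp_bottom", 2001, 30)[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)]
  expect_true(all(patch < 2))
  # without the cold pool the same cells are warmer
  env_nc <- make_environment(tiny_grid(), 2001, cold_pool = FALSE, seed = 101)
  patch_nc <- env_field(env_nc, "temp_bottom", 2001, 30)[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)]
  expect_true(all(patch_nc > patch))
})

test_that("identical seeds give bit-identical archives and trip sets", {
  g <- tiny_grid()
  e1 <- make_environment(g, 2001:2002, seed = 42)
  e2 <- make_environment(g, 2001:2002, seed = 42)
  expect_identical(e1$weekly, e2$weekly)
  expect_identical(e1$phl_avg, e2$phl_avg)
  t1 <- simulate_tracks(e1, 3, 2, seed = 7)
  t2 <- simulate_tracks(e2, 3, 2, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_tracks(e1, 3, 2, seed = 8)
  expect_false(identical(t1$lon, t3$lon))
})

test_that("trips start and end at the rookery on a strict hourly clock", {
  trips <- study_trips()
  for (tid in unique(trips$trip_id)) {
    tt <- trips[trips$trip_id == tid]
    data.table::setorder(tt, timestamp)
    expect_equal(tt$lon[1], tt$rookery_lon[1], tolerance = 1e-9)
    expect_equal(tt$lat[1], tt$rookery_lat[1], tolerance = 1e-9)
    expect_equal(tt$lon[nrow(tt)], tt$rookery_lon[1], tolerance = 1e-9)
    expect_equal(tt$lat[nrow(tt)], tt$rookery_lat[1], tolerance = 1e-9)
    dt <- diff(as.numeric(tt$timestamp))
    expect_true(all(dt == 3600))
    expect_gte(nrow(tt) - 1, 24)  # duration >= 24 h
  }
})

test_that("null track steps have the configured lag-1 autocorrelation", {
  env <- tiny_env()
  tr <- simulate_tracks(env, 1, 1, duration_mean_d = 45, duration_sd_d = 0.1,
                        step_params = list(mean_step_km = 4.5, ar = 0.75),
                        seed = 5)
  s <- cbind(diff(tr$lon), diff(tr$lat))
  expect_gt(nrow(s), 1000)
  for (k in 1:2) {
    ac <- stats::cor(s[-1, k], s[-nrow(s), k])
    expect_lt(abs(ac - 0.75), 0.1)
  }
})

test_that("null step lengths match a fresh draw from the same null model", {
  env <- tiny_env()
  tr <- simulate_tracks(env, 3, 2, duration_mean_d = 8, duration_sd_d = 1,
                        seed = 31)
  s1 <- sqrt(diff(tr$lon)^2 + diff(tr$lat)^2)
  tr2 <- simulate_tracks(env, 3, 2, duration_mean_d = 8, duration_sd_d = 1,
                         seed = 77)
  s2 <- sqrt(diff(tr2$lon)^2 + diff(tr2$lat)^2)
  n <- 500
  set.seed(9)
  p <- suppressWarnings(stats::ks.test(sample(s1, n), sample(s2, n))$p.value)
  expect_gt(p, 0.01)
})

test_that("strong depth-band selection concentrates positions in the band", {
  env <- study_env()
  g <- env$grid
  frac_band <- function(tr) {
    cell <- ll_to_cell(g, tr$lon, tr$lat)
    ok <- !is.na(cell$row)
    dep <- env$bathymetry[cbind(cell$row[ok], cell$col[ok])]
    mean(dep >= 75 & dep <= 200)
  }
  sel <- selection_spec(list(
    bathymetry = list(x = c(0, 60, 75, 200, 260, 4000),
                      w = c(0.01, 0.01, 1, 1, 0.01, 0.01))), strength = 3)
  sp <- list(mean_step_km = 4.5, ar = 0.5)
  f_sel <- frac_band(simulate_tracks(env, 8, 2, selection = sel,
                                     n_candidates = 25, step_params = sp,
                                     seed = 2))
  f_null <- frac_band(simulate_tracks(env, 8, 2, step_params = sp, seed = 2))
  expect_gte(f_sel, 0.70)
  expect_lt(f_null, 0.45)
})

test_that("catch grid modes conserve totals and respect masks", {
  env <- tiny_env()
  cg <- make_catch_grid(env, "uniform", total_t = 1234)
  expect_equal(sum(cg$catch), 1234, tolerance = 1e-9)
  expect_true(all(cg$catch >= 0))

  sw <- make_catch_grid(env, "shelf-weighted", total_t = 500)
  expect_equal(sum(sw$catch), 500, tolerance = 1e-9)
  # brute-force: coarse cells containing no fine shelf cell carry no catch
  fine <- env$grid
  lons <- grid_lons(fine); lats <- grid_lats(fine)
  has_shelf <- matrix(FALSE, sw$grid$nlat, sw$grid$nlon)
  for (r in seq_len(fine$nlat)) for (c in seq_len(fine$nlon)) {
    if (env$habitat[r, c] != "shelf") next
    idx <- ll_to_cell(sw$grid, lons[c], lats[r])
    if (!is.na(idx$row)) has_shelf[idx$row, idx$col] <- TRUE
  }
  expect_true(all(sw$catch[!has_shelf] == 0))
  expect_true(all(sw$catch[has_shelf] > 0))

  fm <- make_catch_grid(env, "from-mask", total_t = 100, cells = NULL)
  expect_true(all(fm$catch == 0))
  fm2 <- make_catch_grid(env, "from-mask", total_t = 100,
                         cells = data.frame(row = c(2, 3), col = c(4, 4)))
  expect_equal(sum(fm2$catch), 100, tolerance = 1e-9)
  expect_equal(sum(fm2$catch > 0), 2)
})

test_that("projection archive recovers configured bias and drift", {
  g <- tiny_grid()
  env <- make_environment(g, 2001:2004, seed = 11)
  # zero bias/drift, same seed: historical segment identical to hindcast
  p0 <- make_projection_archive(env, historical_years = 2001:2004,
                                future_years = 2011:2012, seed = 11)
  for (v in c("temp_surface", "phl"))
    expect_equal(p0$weekly[[v]][, , , 1:4], env$weekly[[v]],
                 tolerance = 1e-12)
  # +2 degC surface bias recovered by climatology differencing
  p2 <- make_projection_archive(env, historical_years = 2001:2004,
                                future_years = 2011:2012,
                                esm_bias = c(temp_surface = 2), seed = 12)
  clim_f <- apply(p2$weekly$temp_surface[, , 27:44, 1:4], c(1, 2), mean)
  clim_h <- apply(env$weekly$temp_surface[, , 27:44, ], c(1, 2), mean)
  expect_lt(abs(mean(clim_f - clim_h) - 2), 0.15)
  # linear drift: future-decade mean minus historical mean tracks the trend
  pd <- make_projection_archive(env, drift = c(temp_surface = 1),
                                historical_years = 2001:2004,
                                future_years = 2021:2024, seed = 13)
  m_hist <- mean(pd$weekly$temp_surface[, , , 1:4])
  m_fut <- mean(pd$weekly$temp_surface[, , , 5:8])
  expect_equal(m_fut - m_hist, 2.0, tolerance = 0.2)  # 20 years * 1/decade
})

test_that("archive and trip-set text round trips preserve the data", {
  env <- make_environment(tiny_grid(16, 16), 2001, seed = 3)
  d <- file.path(tempdir(), "envarc")
  write_env_archive(env, d)
  env2 <- read_env_archive(d)
  expect_equal(env2$bathymetry, env$bathymetry, tolerance = 1e-9)
  expect_equal(env2$weekly$temp_bottom, env$weekly$temp_bottom, tolerance = 1e-9)
  expect_identical(env2$habitat, env$habitat)
  expect_identical(env2$mismatch, env$mismatch)

  tr <- simulate_tracks(env, 2, 1, seed = 5)
  f <- file.path(tempdir(), "trips.csv")
  write_trip_set(tr, f)
  tr2 <- read_trip_set(f)
  expect_equal(tr2$lon, tr$lon, tolerance = 1e-9)
  expect_identical(as.numeric(tr2$timestamp), as.numeric(tr$timestamp))

  cg <- make_catch_grid(env, "uniform", total_t = 10)
  fc <- file.path(tempdir(), "catch.csv")
  write_catch_grid(cg, fc)
  cg2 <- read_catch_grid(fc)
  expect_equal(cg2$catch, cg$catch, tolerance = 1e-9)
})
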