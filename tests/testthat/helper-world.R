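# Shared synthetic worlds, built once per test run and memoized.

tiny_grid <- function(nlon = 24, nlat = 24)
  grid_spec(-171, 55.5, 0.18, 0.09, nlon, nlat)

study_grid <- function() grid_spec(-173.9, 54.05, 0.18, 0.09, 56, 64)

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- build()
  .world_cache[[key]]
}

# small two-year archive on the tiny grid (fast; most module tests)
tiny_env <- function() memo("tiny_env", function()
  make_environment(tiny_grid(), 2001:2002, seed = 101))

# study-scale archive and a null trip set over it (shared by several files)
study_env <- function() memo("study_env", function()
  make_environment(study_grid(), 2001:2004, seed = 101))

study_trips <- function() memo("study_trips", function()
  simulate_tracks(study_env(), 6, 2, seed = 202))

study_replicates <- function() memo("study_reps", function()
  build_replicates(study_trips(), study_env(), n_replicates = 3,
                   n_candidates = 40, seed = 303))

# small labelled dataset with trip structure for model-level tests:
# presence probability driven by covariate x1 only
toy_model_data <- function(n_trips = 12, rows_per_trip = 40, seed = 7,
                           beta = 3) {
  set.seed(seed)
  d <- data.table::data.table(
    trip_id = rep(sprintf("T%02d", seq_len(n_trips)), each = rows_per_trip),
    year = rep(rep(2001:2004, length.out = n_trips), each = rows_per_trip),
    x1 = rnorm(n_trips * rows_per_trip),
    x2 = rnorm(n_trips * rows_per_trip),
    x3 = rnorm(n_trips * rows_per_trip))
  p <- stats::plogis(beta * d$x1)
  d$label <- ifelse(runif(nrow(d)) < p, "presence", "absence")
  d
}

# small fitted shelf ensemble shared by the prediction/projection tests
small_ensemble <- function() memo("small_ens", function()
  fit_ensemble(study_replicates()$shelf, habitat = "shelf", k = 5,
               ntree = 60, seed = 9))

# full acceptance-scale null world: 27-year archive (the span of a long
# telemetry program), 40 animals x 3 trips with no habitat selection, and
# 10 replicate datasets. Built once and shared by the acceptance criteria
# and the exchangeability invariant.
null_world <- function() memo("null_world", function() {
  env <- make_environment(study_grid(), 1992:2018, seed = 11)
  trips <- simulate_tracks(env, 40, 3, seed = 12)
  reps <- build_replicates(trips, env, n_replicates = 10,
                          n_candidates = 100, seed = 13)
  list(env = env, trips = trips, reps = reps)
})
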