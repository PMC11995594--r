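## End-to-end orchestration with a validated, YAML-serializable
## configuration. The analysis constants default to the pipeline's published
## settings (12-h trim, 100 candidate tracks, 6-day filter window, 10
## replicates, mtry grid 2/3/4, 500 trees, node size 1, 10 folds, Jul-Oct,
## 375-km accessibility radius, top-25% core quantile).

#' Build a validated pipeline configuration
#'
#' @param outdir Output directory for artifacts.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param grid List of `grid_spec` arguments for the simulated archive.
#' @param years Simulated years.
#' @param animals,trips_per_animal Telemetry simulation size.
#' @param selection_strength Selection strength for the simulated tracks.
#' @param depth_rule Shelf/basin split depth (m).
#' @param trim_hours,n_candidates,window_days,n_replicates Pseudo-absence
#'   settings.
#' @param mtry_grid,trees,node_size,cv_folds Model settings.
#' @param weeks Prediction weeks (default Jul-Oct).
#' @param crop_radius_km Accessibility radius.
#' @param core_quantile Core-habitat quantile.
#' @param warm_years,cold_years Year-class lists.
#' @param scenarios Projection scenario labels.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "cpfhabitat_out", seed = 1,
                            grid = list(lon0 = -173.9, lat0 = 54.05,
                                        dlon = 0.18, dlat = 0.09,
                                        nlon = 56, nlat = 64),
                            years = 2001:2002, animals = 8,
                            trips_per_animal = 2, selection_strength = 0,
                            depth_rule = 200, trim_hours = 12,
                            n_candidates = 100, window_days = 6,
                            n_replicates = 10, mtry_grid = c(2, 3, 4),
                            trees = 500, node_size = 1, cv_folds = 10,
                            weeks = 27:44, crop_radius_km = 375,
                            core_quantile = 0.75,
                            warm_years = default_year_classes()$warm,
                            cold_years = default_year_classes()$cold,
                            scenarios = "ssp_demo") {
  cfg <- list(outdir = outdir, seed = seed, grid = grid, years = years,
              animals = animals, trips_per_animal = trips_per_animal,
              selection_strength = selection_strength,
              depth_rule = depth_rule, trim_hours = trim_hours,
              n_candidates = n_candidates, window_days = window_days,
              n_replicates = n_replicates, mtry_grid = mtry_grid,
              trees = trees, node_size = node_size, cv_folds = cv_folds,
              weeks = weeks, crop_radius_km = crop_radius_km,
              core_quantile = core_quantile, warm_years = warm_years,
              cold_years = cold_years, scenarios = scenarios)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks positivity of all numeric parameters, that the core quantile is in
#' (0, 1), and that the warm and cold year lists are disjoint. Violations
#' raise errors naming the offending field.
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  pos <- c("trim_hours", "n_candidates", "window_days", "n_replicates",
           "trees", "node_size", "cv_folds", "crop_radius_km", "depth_rule",
           "animals", "trips_per_animal")
  for (f in pos) {
    v <- cfg[[f]]
    ok <- is.numeric(v) && length(v) > 0 &&
      (if (f == "trim_hours") all(v >= 0) else all(v > 0))
    if (!ok) stop("config field ", f, " must be positive")
  }
  if (!is.numeric(cfg$core_quantile) || cfg$core_quantile <= 0 ||
      cfg$core_quantile >= 1)
    stop("config field core_quantile must lie in (0, 1)")
  if (length(intersect(cfg$warm_years, cfg$cold_years)) > 0)
    stop("config fields warm_years/cold_years must be disjoint")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @param cfg A `pipeline_config`.
#' @return `load_config` returns a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the pipeline
#'
#' Executes the requested stages, writing artifacts under `cfg$outdir`:
#' `simulate` (environment archive, trip CSV, catch CSV),
#' `build-data` (replicate dataset CSVs per habitat),
#' `fit` (ensemble RDS + JSON metadata sidecars, metrics CSV),
#' `predict`/`core` (hindcast mean surface CSVs, core masks, thresholds
#' JSON), `overlap` (summary JSON), `project` (corrected projection and
#' change-metrics CSV), `exdet` (extrapolation summary JSON), or `all`.
#' A run manifest (config, seed, timings, artifact checksums) is written as
#' `manifest.json`; identical config + seed reproduce identical artifacts.
#'
#' @param cfg A `pipeline_config`.
#' @param steps Character vector of stages, or `"all"`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, steps = "all") {
  validate_config(cfg)
  all_steps <- c("simulate", "build-data", "fit", "predict", "core",
                 "overlap", "project", "exdet")
  if (identical(steps, "all")) steps <- all_steps
  bad <- setdiff(steps, all_steps)
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ","))
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time(); timings <- list(); artifacts <- character(0)
  state <- new.env(parent = emptyenv())

  need_env <- function() {
    if (is.null(state$env)) {
      p <- file.path(out, "env_archive")
      state$env <- if (file.exists(file.path(p, "header.json")))
        read_env_archive(p)
      else stop("missing environment archive; run the 'simulate' step first")
    }
    state$env
  }
  need_reps <- function() {
    if (is.null(state$reps)) {
      f <- file.path(out, "replicates.rds")
      if (!file.exists(f)) stop("missing replicate datasets; run 'build-data' first")
      state$reps <- readRDS(f)
    }
    state$reps
  }
  need_ens <- function() {
    if (is.null(state$ens)) {
      f <- file.path(out, "ensembles.rds")
      if (!file.exists(f)) stop("missing ensembles; run 'fit' first")
      state$ens <- readRDS(f)
    }
    state$ens
  }
  stamp <- function(step, files) {
    timings[[step]] <<- as.numeric(Sys.time() - t0, units = "secs")
    artifacts <<- c(artifacts, files)
  }

  for (step in steps) {
    if (step == "simulate") {
      g <- do.call(grid_spec, cfg$grid)
      state$env <- make_environment(g, cfg$years,
                                    seed = derive_seed(cfg$seed, "env"))
      sel <- if (cfg$selection_strength > 0)
        depth_band_selection(cfg$selection_strength) else selection_spec()
      state$trips <- simulate_tracks(state$env, cfg$animals,
                                     cfg$trips_per_animal, selection = sel,
                                     seed = derive_seed(cfg$seed, "tracks"))
      state$catch <- make_catch_grid(state$env, "shelf-weighted",
                                     seed = derive_seed(cfg$seed, "catch"))
      write_env_archive(state$env, file.path(out, "env_archive"))
      write_trip_set(state$trips, file.path(out, "trips.csv"))
      write_catch_grid(state$catch, file.path(out, "catch.csv"))
      stamp(step, c("env_archive/header.json", "trips.csv", "catch.csv"))
    } else if (step == "build-data") {
      env <- need_env()
      if (is.null(state$trips)) state$trips <- read_trip_set(file.path(out, "trips.csv"))
      state$reps <- build_replicates(state$trips, env,
                                     n_replicates = cfg$n_replicates,
                                     n_candidates = cfg$n_candidates,
                                     window_days = cfg$window_days,
                                     trim_hours = cfg$trim_hours,
                                     seed = derive_seed(cfg$seed, "reps"))
      saveRDS(state$reps, file.path(out, "replicates.rds"))
      for (h in names(state$reps))
        data.table::fwrite(data.table::rbindlist(state$reps[[h]]),
                           file.path(out, paste0("replicates_", h, ".csv")))
      stamp(step, paste0("replicates_", names(state$reps), ".csv"))
    } else if (step == "fit") {
      reps <- need_reps()
      ## a habitat needs >= 2 trips with data to be modelled (mirrors the
      ## study's missing basin model for one complex)
      viable <- vapply(reps, function(h) {
        pooled <- data.table::rbindlist(h)
        nrow(pooled) > 0 && length(unique(pooled$trip_id)) >= 2 &&
          all(vapply(h, function(d) length(unique(d$label)) == 2 &&
                       length(unique(d$trip_id)) >= 2, TRUE))
      }, TRUE)
      reps <- reps[viable]
      state$ens <- lapply(names(reps), function(h)
        fit_ensemble(reps[[h]], habitat = h, mtry_grid = cfg$mtry_grid,
                     k = cfg$cv_folds, ntree = cfg$trees,
                     min_node = cfg$node_size,
                     seed = derive_seed(cfg$seed, paste0("fit", h))))
      names(state$ens) <- names(reps)
      saveRDS(state$ens, file.path(out, "ensembles.rds"))
      for (h in names(state$ens)) {
        e <- state$ens[[h]]
        jsonlite::write_json(
          list(habitat = h, scope = e$scope, mtry = e$mtry,
               auc_cv = e$auc_cv, auc_time = e$auc_time,
               variables = e$variables, seed = cfg$seed),
          file.path(out, paste0("ensemble_", h, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
      utils::write.csv(ensemble_metrics(state$ens),
                       file.path(out, "metrics.csv"), row.names = FALSE)
      stamp(step, c("ensembles.rds", "metrics.csv"))
    } else if (step %in% c("predict", "core")) {
      env <- need_env(); ens <- need_ens()
      if (is.null(state$hind)) {
        cx <- default_complexes(env)
        center <- c(mean(cx$lon), mean(cx$lat))
        state$center <- center
        state$hind <- lapply(ens, function(e) {
          hs <- hindcast_surfaces(e, env, weeks = cfg$weeks,
                                  year_classes = list(warm = cfg$warm_years,
                                                      cold = cfg$cold_years))
          hs$mean_cropped <- accessibility_crop(hs$mean, center,
                                                cfg$crop_radius_km)
          hs
        })
      }
      if (step == "predict") {
        for (h in names(state$hind))
          write_surface(state$hind[[h]]$mean_cropped,
                        file.path(out, paste0("hindcast_mean_", h, ".csv")))
        stamp(step, paste0("hindcast_mean_", names(state$hind), ".csv"))
      } else {
        state$cores <- lapply(state$hind, function(hs)
          core_threshold(hs$mean_cropped, q = cfg$core_quantile))
        jsonlite::write_json(
          lapply(state$cores, function(cm)
            list(tau = cm$tau, area_km2 = cm$area_km2,
                 n_core = sum(cm$core, na.rm = TRUE))),
          file.path(out, "core_thresholds.json"), auto_unbox = TRUE, digits = NA)
        stamp(step, "core_thresholds.json")
      }
    } else if (step == "overlap") {
      env <- need_env()
      if (is.null(state$cores)) stop("missing core maps; run 'core' first")
      if (is.null(state$catch)) state$catch <- read_catch_grid(file.path(out, "catch.csv"))
      core <- union_core(state$cores)
      ov <- overlap_stats(core, env$grid, state$catch)
      jsonlite::write_json(
        list(prop_catch_in_core = ov$prop_catch_in_core,
             pct_core_area_fished = ov$pct_core_area_fished,
             total_catch_t = ov$total_catch_t,
             core_area_km2 = ov$core_area_km2),
        file.path(out, "overlap.json"), auto_unbox = TRUE, digits = NA)
      stamp(step, "overlap.json")
    } else if (step == "project") {
      env <- need_env(); ens <- need_ens()
      if (is.null(state$cores)) stop("missing core maps; run 'core' first")
      fut <- max(env$years) + 1:2
      proj <- make_projection_archive(env, drift = c(temp_surface = 1),
                                      historical_years = env$years,
                                      future_years = fut,
                                      esm_bias = c(temp_surface = 1.5),
                                      seed = derive_seed(cfg$seed, "proj"))
      corr <- bias_correct(proj, env, env$years)
      cx <- default_complexes(env)
      rows <- lapply(names(ens), function(h) {
        ps <- project_suitability(ens[[h]], corr, fut, weeks = cfg$weeks)
        ps <- accessibility_crop(ps, state$center, cfg$crop_radius_km)
        cm <- change_metrics(state$hind[[h]]$mean_cropped, ps,
                             state$cores[[h]],
                             c(cx$lon[1], cx$lat[1]))
        cbind(habitat = h, scenario = cfg$scenarios[1], as.data.frame(cm))
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(out, "change_metrics.csv"), row.names = FALSE)
      state$proj_corrected <- corr; state$proj_years <- fut
      stamp(step, "change_metrics.csv")
    } else if (step == "exdet") {
      env <- need_env()
      corr <- state$proj_corrected
      if (is.null(corr)) stop("missing corrected projection; run 'project' first")
      vars <- c("temp_bottom", "temp_surface", "phl")
      ref <- do.call(rbind, lapply(env$years, function(y)
        do.call(rbind, lapply(intersect(cfg$weeks, env$weeks), function(w)
          vapply(vars, function(v) as.vector(env_field(env, v, y, w)),
                 numeric(env$grid$nlat * env$grid$nlon))))))
      res <- lapply(state$proj_years, function(y)
        exdet(ref, vapply(vars, function(v)
          as.vector(env_field(corr, v, y, cfg$weeks[1])),
          numeric(env$grid$nlat * env$grid$nlon))))
      sm <- exdet_summary(res, scenario = cfg$scenarios[1])
      jsonlite::write_json(list(scenario = sm$scenario,
                                fractions = as.list(sm$fractions), n = sm$n),
                           file.path(out, "exdet_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      stamp(step, "exdet_summary.json")
    }
  }
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   steps = steps, timings_s = timings,
                   checksums = as.list(tools::md5sum(
                     file.path(out, intersect(artifacts, list.files(out))))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
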