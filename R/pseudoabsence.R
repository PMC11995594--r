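## Pseudo-absence machinery: per-trip first-order vector-autoregressive (VAR)
## fit on hourly step vectors, endpoint-pinned simulation of candidate null
## tracks, spatiotemporal exclusion filtering against the presence data,
## partner selection, and assembly of replicate 1:1 presence/absence
## datasets.

#' Fit a first-order vector-autoregressive model to a trip
#'
#' The model is on hourly step vectors `s_t = x_t - x_(t-1)` (degrees):
#' `s_t - mu = A (s_(t-1) - mu) + eps_t`, `eps_t ~ N(0, Sigma)`, estimated by
#' least squares. Degenerate (zero-variance) step sequences return `A = 0`,
#' `mu` = the constant step, and `Sigma` floored at `1e-12 * I` with a
#' warning.
#'
#' @param trip data.frame of one trip's records ordered in time, with `lon`,
#'   `lat` columns at 1-h spacing (>= 9 records, i.e. >= 8 steps).
#' @return A `var_params` list: `mu` (2-vector), `A` (2x2), `Sigma` (2x2).
#' @export
fit_var <- function(trip) {
  s <- cbind(diff(trip$lon), diff(trip$lat))
  n <- nrow(s)
  if (n < 8) stop("trip must have >= 8 hourly steps")
  degenerate <- all(apply(s, 2, stats::var) < 1e-20)
  if (!degenerate) {
    X <- cbind(1, s[-n, , drop = FALSE])
    Y <- s[-1, , drop = FALSE]
    B <- tryCatch(solve(crossprod(X), crossprod(X, Y)), error = function(e) NULL)
    degenerate <- is.null(B)
  }
  if (degenerate) {
    warning("degenerate step sequence; Sigma floored at 1e-12")
    return(structure(list(mu = colMeans(s), A = matrix(0, 2, 2),
                          Sigma = diag(1e-12, 2)), class = "var_params"))
  }
  A <- t(B[2:3, , drop = FALSE])
  cvec <- B[1, ]
  mu <- tryCatch(solve(diag(2) - A, cvec), error = function(e) colMeans(s))
  resid <- Y - X %*% B
  Sigma <- crossprod(resid) / max(1, nrow(resid) - 3)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12) {
    warning("near-singular innovation covariance; floored at 1e-12")
    Sigma <- Sigma + diag(1e-12 - min(ev, 0), 2)
  }
  structure(list(mu = mu, A = A, Sigma = Sigma), class = "var_params")
}

## lower-triangular factor used to draw VAR innovations
sigma_chol <- function(Sigma) {
  t(tryCatch(chol(Sigma), error = function(e) chol(Sigma + diag(1e-12, 2))))
}

#' Simulate endpoint-pinned candidate null tracks for a trip
#'
#' Simulates `n` tracks from the trip's fitted VAR step model, each with the
#' trip's exact timestamp vector and start position. After free simulation
#' the closure error (simulated end minus the trip's true end) is removed by
#' subtracting `error / n_steps` from every step, so every candidate starts
#' and ends exactly where the trip does. Candidates whose mean step length is
#' outside a factor [0.5, 2] of the real trip's are re-simulated (up to
#' `max_retries` rounds); any still outside are kept and flagged
#' `speed_mismatch`.
#'
#' @param params A `var_params` from [fit_var()].
#' @param trip The (trimmed) trip records: `timestamp`, `lon`, `lat`.
#' @param n Number of candidate tracks (default 100).
#' @param seed Integer seed.
#' @param max_retries Re-simulation rounds for speed-mismatched candidates.
#' @return data.table with columns `sim_id`, `timestamp`, `lon`, `lat`;
#'   attribute `speed_mismatch` is a logical vector over candidates.
#' @export
simulate_candidates <- function(params, trip, n = 100, seed = 1, max_retries = 20) {
  stopifnot(n >= 1)
  T_pos <- nrow(trip)
  nsteps <- T_pos - 1L
  real_steps <- cbind(diff(trip$lon), diff(trip$lat))
  real_msl <- mean(sqrt(rowSums(real_steps^2)))
  start <- c(trip$lon[1], trip$lat[1])
  end <- c(trip$lon[T_pos], trip$lat[T_pos])
  L <- sigma_chol(params$Sigma)
  set.seed(derive_seed(seed, "cand"))

  sim_block <- function(m) {
    ## simulate m candidates jointly; returns list(lon, lat) matrices m x T_pos
    steps <- array(0, c(m, nsteps, 2))
    s <- matrix(rep(params$mu, each = m), m, 2) +
      matrix(stats::rnorm(2 * m), m, 2) %*% t(L)
    for (t in seq_len(nsteps)) {
      eps <- matrix(stats::rnorm(2 * m), m, 2) %*% t(L)
      s <- sweep(sweep(s, 2, params$mu) %*% t(params$A), 2, params$mu, "+") + eps
      steps[, t, ] <- s
    }
    tot <- apply(steps, c(1, 3), sum)
    err <- sweep(tot, 2, (end - start))   # closure error per candidate
    steps <- sweep(steps, c(1, 3), err / nsteps)
    sl <- matrix(steps[, , 1], nrow = m)
    sa <- matrix(steps[, , 2], nrow = m)
    lon <- cbind(start[1], start[1] + t(apply(sl, 1, cumsum)))
    lat <- cbind(start[2], start[2] + t(apply(sa, 1, cumsum)))
    list(lon = lon, lat = lat)
  }

  sim <- sim_block(n)
  msl <- function(lon, lat)
    rowMeans(sqrt(diff(t(lon))^2 + diff(t(lat))^2))
  bad <- if (real_msl > 0) {
    r <- msl(sim$lon, sim$lat) / real_msl
    r < 0.5 | r > 2
  } else rep(FALSE, n)
  tries <- 0L
  while (any(bad) && tries < max_retries) {
    tries <- tries + 1L
    redo <- sim_block(sum(bad))
    sim$lon[bad, ] <- redo$lon
    sim$lat[bad, ] <- redo$lat
    r <- msl(sim$lon, sim$lat) / real_msl
    bad <- r < 0.5 | r > 2
  }
  out <- data.table::data.table(
    sim_id = rep(seq_len(n), each = T_pos),
    timestamp = rep(trip$timestamp, n),
    lon = as.vector(t(sim$lon)),
    lat = as.vector(t(sim$lat)))
  data.table::setattr(out, "speed_mismatch", bad)
  out
}

## encode (row, col, day) triples as exact doubles for fast set membership
cell_day_key <- function(row, col, day) (row * 3000 + col) * 1e6 + day

#' Spatiotemporal exclusion filter for candidate positions
#'
#' Removes every candidate position that falls in the same or an adjacent
#' (8-neighbour) grid cell as any presence point dated within
#' `window_days` days (|candidate date - presence date| <= `window_days`).
#' Removal is per position; candidates keep their surviving positions.
#'
#' @param cands data.table of candidate positions with `row`, `col`, `date`
#'   columns (e.g. candidates passed through [assign_points()]).
#' @param presence data.table of presence points with `row`, `col`, `date`.
#' @param window_days Temporal window (default 6 days).
#' @return `cands` with offending rows removed.
#' @export
filter_candidates <- function(cands, presence, window_days = 6) {
  if (nrow(cands) == 0 || nrow(presence) == 0) return(cands)
  pk <- unique(data.table::data.table(
    row = presence$row, col = presence$col, day = as.integer(presence$date)))
  offs <- expand.grid(dr = -1:1, dc = -1:1, dd = -window_days:window_days)
  keys <- unlist(lapply(seq_len(nrow(offs)), function(i)
    cell_day_key(pk$row + offs$dr[i], pk$col + offs$dc[i], pk$day + offs$dd[i])))
  ck <- cell_day_key(cands$row, cands$col, as.integer(cands$date))
  cands[!(ck %in% keys)]
}

#' Rank surviving candidates and pick a replicate's partner track
#'
#' Candidates are ranked by their number of distinct days with at least one
#' surviving position (ties broken by lowest candidate index). Replicate 1
#' takes the top-ranked candidate; replicates r > 1 take successive items of
#' a seeded random permutation of the remaining eligible candidates (cycling
#' if there are fewer candidates than replicates), so each replicate pairs
#' the trip with a different simulated track whenever possible.
#'
#' @param cands Filtered candidate positions (`sim_id`, `date` columns).
#' @param replicate Replicate index (1-based).
#' @param seed Integer seed for the permutation (fixed per trip).
#' @return The selected candidate index, or `NA` if no candidate survives.
#' @export
select_partner <- function(cands, replicate = 1, seed = 1) {
  if (nrow(cands) == 0) return(NA_integer_)
  days <- cands[, list(ndays = length(unique(date))), by = "sim_id"]
  days <- days[order(-days$ndays, days$sim_id)]
  eligible <- days$sim_id
  if (replicate == 1 || length(eligible) == 1) return(eligible[1])
  rest <- eligible[-1]
  set.seed(derive_seed(seed, "partnerperm"))
  perm <- rest[sample.int(length(rest))]
  perm[((replicate - 2L) %% length(perm)) + 1L]
}

#' Build replicate presence/pseudo-absence datasets
#'
#' Runs the full pseudo-absence pipeline: trim trip ends, assign presence
#' points to cells (dropping mismatch-zone and off-grid records), fit a VAR
#' to each trip and simulate `n_candidates` endpoint-pinned null tracks,
#' filter candidate positions against all presence points with the
#' same/adjacent-cell `window_days`-day rule, then assemble `n_replicates`
#' datasets: one presence per trip-day (uniformly sampled), a partner
#' candidate per trip (different per replicate), partner positions
#' down-sampled to one per day, and days present in only one member of the
#' pair dropped from both. Pairing and day matching are done within habitat,
#' so each habitat's dataset is exactly 1:1 presence:absence. Covariates are
#' attached via [extract_covariates()].
#'
#' @param trips A `trip_set`.
#' @param env An `env_archive`.
#' @param n_replicates Number of replicate datasets (default 10).
#' @param n_candidates Candidate null tracks per trip (default 100).
#' @param window_days Exclusion-filter window (default 6).
#' @param trim_hours Trip-end trim (default 12).
#' @param seed Master seed.
#' @return Named list by habitat (`shelf`, `basin`; habitats with no rows are
#'   omitted). Each element is a list of `n_replicates` data.tables with
#'   columns `replicate, habitat, label, trip_id, animal_id, complex, date,
#'   year, lon, lat, row, col, week` plus the covariates. Attribute
#'   `excluded_trips` lists trips with no surviving candidate.
#' @export
build_replicates <- function(trips, env, n_replicates = 10, n_candidates = 100,
                             window_days = 6, trim_hours = 12, seed = 1) {
  trimmed <- trim_trip_ends(trips, trim_hours)
  pts <- assign_points(trimmed, env)
  trip_ids <- unique(trimmed$trip_id)
  excluded <- character(0)

  ## per-trip: simulate + locate + filter candidates once (shared across
  ## replicates); presence points grouped per trip
  per_trip <- list()
  for (tid in trip_ids) {
    tr <- trimmed[trimmed$trip_id == tid]
    data.table::setorder(tr, timestamp)
    if (nrow(tr) < 9) { excluded <- c(excluded, tid); next }
    pres <- pts[pts$trip_id == tid]
    if (nrow(pres) == 0) { excluded <- c(excluded, tid); next }
    vp <- fit_var(tr)
    cand <- simulate_candidates(vp, tr, n = n_candidates,
                                seed = derive_seed(seed, paste0("sim", tid)))
    cell <- ll_to_cell(env$grid, cand$lon, cand$lat)
    cand$row <- cell$row; cand$col <- cell$col
    keep <- !is.na(cell$row)
    cand <- cand[keep]
    keep <- !env$mismatch[cbind(cand$row, cand$col)]
    cand <- cand[keep]
    cand$date <- as.Date(cand$timestamp, tz = "UTC")
    cand <- filter_candidates(cand, pts, window_days)
    if (nrow(cand) == 0) { excluded <- c(excluded, tid); next }
    cand$habitat <- env$habitat[cbind(cand$row, cand$col)]
    cand$year <- as.integer(format(cand$date, "%Y"))
    per_trip[[tid]] <- list(trip = tr[1], pres = pres, cand = cand)
  }

  sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
  habitats <- c("shelf", "basin")
  out <- stats::setNames(lapply(habitats, function(h) vector("list", n_replicates)),
                         habitats)
  pairing <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, paste0("replicate", r)))
    rows <- list()
    for (tid in names(per_trip)) {
      pt <- per_trip[[tid]]
      partner <- select_partner(pt$cand, replicate = r,
                                seed = derive_seed(seed, paste0("perm", tid)))
      sel_rows <- which(pt$cand$sim_id == partner)
      cand_r <- pt$cand[sel_rows]
      ## one location per day, uniformly at random, for both members
      pres_d <- pt$pres[, .SD[sample1(seq_len(.N))], by = "date"]
      abs_d <- cand_r[, .SD[sample1(seq_len(.N))], by = "date"]
      pairing[[length(pairing) + 1L]] <- data.table::data.table(
        trip_id = tid, replicate = r, candidate = partner)
      for (h in habitats) {
        p_h <- pres_d[pres_d$habitat == h]
        a_h <- abs_d[abs_d$habitat == h]
        ## days present in only one member of the pair are dropped from both
        keep_p <- p_h$date %in% a_h$date
        keep_a <- a_h$date %in% p_h$date
        if (!any(keep_p)) next
        p_h <- p_h[keep_p]
        a_h <- a_h[keep_a]
        mk <- function(d, label) data.table::data.table(
          replicate = r, habitat = h, label = label, trip_id = tid,
          animal_id = pt$trip$animal_id, complex = pt$trip$complex,
          date = d$date, year = as.integer(format(d$date, "%Y")),
          lon = d$lon, lat = d$lat, row = d$row, col = d$col)
        rows[[length(rows) + 1L]] <- mk(p_h, "presence")
        rows[[length(rows) + 1L]] <- mk(a_h, "absence")
      }
    }
    if (length(rows) == 0) next
    rep_rows <- extract_covariates(data.table::rbindlist(rows), env)
    for (h in habitats)
      out[[h]][[r]] <- rep_rows[rep_rows$habitat == h]
  }
  out <- out[vapply(out, function(h) any(vapply(h, NROW, 1L) > 0), TRUE)]
  attr(out, "excluded_trips") <- unique(excluded)
  attr(out, "pairing") <- data.table::rbindlist(pairing)
  out
}
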