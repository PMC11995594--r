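## Overlap between fine-grid core habitat and a coarse fishery-catch grid.

#' Union of core-habitat maps across complexes
#'
#' Cellwise OR: a fine cell is 1 if it is core habitat for at least one
#' complex, 0 if core for none, NA where no map defines it.
#'
#' @param maps List of `core_habitat_map` objects on a shared grid.
#' @return Logical matrix.
#' @export
union_core <- function(maps) {
  stopifnot(length(maps) >= 1)
  out <- maps[[1]]$core
  for (m in maps[-1]) {
    v <- m$core
    both <- !is.na(out) & !is.na(v)
    out[both] <- out[both] | v[both]
    only_v <- is.na(out) & !is.na(v)
    out[only_v] <- v[only_v]
  }
  out
}

#' Regrid a fine binary core map to a coarse grid
#'
#' Each coarse cell's value is the mean of the fine-cell indicators whose
#' centers fall inside it (fine cells are assigned by center containment;
#' NA fine cells are ignored). Values lie in [0, 1]; coarse cells containing
#' no defined fine cell are NA.
#'
#' @param core Logical fine-grid matrix (e.g. from [union_core()]).
#' @param fine The fine `grid_spec`.
#' @param coarse The coarse `grid_spec` (e.g. a `catch_grid`'s grid).
#' @return Numeric matrix on the coarse grid.
#' @export
regrid_core <- function(core, fine, coarse) {
  lon <- rep(grid_lons(fine), each = fine$nlat)
  lat <- rep(grid_lats(fine), fine$nlon)
  val <- as.vector(core)
  idx <- ll_to_cell(coarse, lon, lat)
  ok <- !is.na(idx$row) & !is.na(val)
  sums <- matrix(0, coarse$nlat, coarse$nlon)
  cnts <- matrix(0, coarse$nlat, coarse$nlon)
  for (i in which(ok)) {
    sums[idx$row[i], idx$col[i]] <- sums[idx$row[i], idx$col[i]] + val[i]
    cnts[idx$row[i], idx$col[i]] <- cnts[idx$row[i], idx$col[i]] + 1
  }
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Overlap statistics between core habitat and fishery catch
#'
#' The proportion of catch within core habitat is the summed catch over
#' coarse cells with core value > 0 divided by the total catch; the
#' percentage of core area fished is the area of fine core cells lying in
#' coarse cells with catch > 0 divided by the total core area.
#'
#' @param core Logical fine-grid core matrix.
#' @param fine Fine `grid_spec`.
#' @param catch A `catch_grid`.
#' @return An `overlap_result` list: `coarse_core` (regridded values),
#'   `prop_catch_in_core`, `pct_core_area_fished`, `total_catch_t`,
#'   `core_area_km2`. With zero total catch the proportion is `NA` and
#'   flagged via `zero_catch = TRUE`.
#' @export
overlap_stats <- function(core, fine, catch) {
  cc <- regrid_core(core, fine, catch$grid)
  total_catch <- sum(catch$catch)
  in_core <- !is.na(cc) & cc > 0
  prop_catch <- if (total_catch > 0) sum(catch$catch[in_core]) / total_catch
                else NA_real_
  ## fine core cells sitting in fished coarse cells
  area <- cell_area_km2(fine)
  lon <- rep(grid_lons(fine), each = fine$nlat)
  lat <- rep(grid_lats(fine), fine$nlon)
  idx <- ll_to_cell(catch$grid, lon, lat)
  corev <- as.vector(core)
  areav <- as.vector(area)
  is_core <- !is.na(corev) & corev
  fished <- !is.na(idx$row) &
    catch$catch[cbind(pmax(idx$row, 1L), pmax(idx$col, 1L))] > 0
  fished[is.na(idx$row)] <- FALSE
  core_area <- sum(areav[is_core])
  fished_core_area <- sum(areav[is_core & fished])
  structure(list(coarse_core = cc,
                 prop_catch_in_core = prop_catch,
                 pct_core_area_fished = if (core_area > 0)
                   100 * fished_core_area / core_area else NA_real_,
                 total_catch_t = total_catch,
                 core_area_km2 = core_area,
                 zero_catch = total_catch == 0),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %.1f%% of catch in core habitat; %.1f%% of core area fished\n",
              100 * x$prop_catch_in_core, x$pct_core_area_fished))
  invisible(x)
}
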