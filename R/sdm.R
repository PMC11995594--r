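## Habitat-model fitting and evaluation: collinearity screening,
## trip-grouped cross-validated mtry tuning, pooled out-of-fold AUC,
## temporal (by-year) and spatial (cross-complex) transferability, scaled
## Gini importance, and partial dependence.

#' Covariates used by the habitat models
#' @return Character vector of the seven model variables.
#' @export
model_variables <- function() c("bathymetry", "temp_bottom", "temp_surface",
                                "phl", "phl_avg", "ncao_ncas", "eup")

#' Pairwise-correlation screening of covariates
#'
#' Computes pairwise Pearson correlations among the covariates and, for any
#' pair with `|r| > threshold`, drops one variable: a static variable loses
#' to a dynamic one (so bathymetry is dropped when it tracks bottom
#' temperature, as happens over the basin); between two dynamic variables
#' the one appearing later in `vars` is dropped. Pairs are resolved in order
#' of decreasing `|r|`, skipping pairs already resolved.
#'
#' @param dataset data.frame containing the covariate columns.
#' @param threshold Absolute correlation threshold (default 0.7).
#' @param vars Candidate variables (default [model_variables()]).
#' @param static_vars Variables considered static (default `"bathymetry"`).
#' @return List: `retained`, `dropped`, and `flagged` (data.frame
#'   `var1, var2, r` of all pairs exceeding the threshold).
#' @export
collinearity_screen <- function(dataset, threshold = 0.7,
                                vars = model_variables(),
                                static_vars = "bathymetry") {
  vars <- intersect(vars, names(dataset))
  cm <- stats::cor(as.data.frame(dataset)[, vars, drop = FALSE])
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                        r = cm[pairs])
  flagged <- flagged[order(-abs(flagged$r)), , drop = FALSE]
  dropped <- character(0)
  for (i in seq_len(nrow(flagged))) {
    v1 <- flagged$var1[i]; v2 <- flagged$var2[i]
    if (v1 %in% dropped || v2 %in% dropped) next
    loser <- if (v1 %in% static_vars && !(v2 %in% static_vars)) v1
      else if (v2 %in% static_vars && !(v1 %in% static_vars)) v2
      else vars[max(match(c(v1, v2), vars))]
    dropped <- c(dropped, loser)
  }
  list(retained = setdiff(vars, dropped), dropped = dropped, flagged = flagged)
}

## greedy largest-first balancing of groups into k folds; returns fold per group
greedy_folds <- function(group_sizes, k) {
  k <- min(k, length(group_sizes))
  ord <- order(-group_sizes, names(group_sizes))
  fold_tot <- numeric(k)
  assign <- integer(length(group_sizes))
  for (g in ord) {
    f <- which.min(fold_tot)
    assign[g] <- f
    fold_tot[f] <- fold_tot[f] + group_sizes[g]
  }
  stats::setNames(assign, names(group_sizes))
}

#' Trip-grouped cross-validation folds
#'
#' Assigns every row of a trip (presence rows and their paired
#' pseudo-absence rows, which share the trip id) to a single fold. Folds are
#' balanced greedily: trips are placed largest-first into the currently
#' smallest fold. If there are fewer trips than `k`, `k` is reduced.
#'
#' @param dataset data.frame with a `trip_id` column.
#' @param k Number of folds (default 10).
#' @return Integer fold assignment per row.
#' @export
make_trip_folds <- function(dataset, k = 10) {
  sizes <- table(dataset$trip_id)
  fold_by_trip <- greedy_folds(stats::setNames(as.numeric(sizes), names(sizes)), k)
  unname(fold_by_trip[as.character(dataset$trip_id)])
}

#' Area under the ROC curve (rank-based)
#'
#' Equals the Mann-Whitney U statistic divided by `n_pos * n_neg`, with tied
#' scores counted 1/2 (so constant scores give 0.5).
#'
#' @param labels Logical (or coercible) vector, `TRUE` = presence.
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

rf_matrix <- function(dataset, vars) {
  xm <- as.matrix(as.data.frame(dataset)[, vars, drop = FALSE])
  storage.mode(xm) <- "double"
  xm
}

## pooled out-of-fold probabilities for one mtry value
oof_scores <- function(xm, y, folds, mtry, ntree, min_node, seed) {
  out <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    set.seed(derive_seed(seed, paste0("fold", f, "mtry", mtry)))
    m <- random_forest(xm[!hold, , drop = FALSE], y[!hold], ntree = ntree,
                       mtry = mtry, min_node = min_node)
    out[hold] <- rf_predict_cpp(m$trees, xm[hold, , drop = FALSE])
  }
  out
}

#' Tune mtry by trip-grouped cross-validation and fit the final model
#'
#' For each candidate `mtry`, out-of-fold predicted probabilities are pooled
#' across folds and a single AUC is computed; the `mtry` with the highest
#' pooled AUC wins (ties go to the smaller value). The final forest is refit
#' on the full dataset with the chosen `mtry`.
#'
#' @param dataset Replicate dataset rows (`label`, `trip_id`, covariates).
#' @param folds Integer fold assignment per row (e.g. [make_trip_folds()]).
#' @param mtry_grid Candidate values (default 2, 3, 4).
#' @param vars Covariates to use.
#' @param ntree,min_node Forest size and node size (defaults 500 and 1).
#' @param seed Integer seed.
#' @return List: `model` (`cpf_rf`), `mtry`, `auc_cv`, `oof` (pooled
#'   out-of-fold scores at the chosen mtry), `auc_by_mtry`.
#' @export
tune_and_fit <- function(dataset, folds, mtry_grid = c(2, 3, 4),
                         vars = model_variables(), ntree = 500, min_node = 1,
                         seed = 1) {
  y <- as.integer(dataset$label == "presence")
  if (length(unique(y)) < 2) stop("dataset must contain both labels")
  if (length(unique(dataset$trip_id)) < 2) stop("need >= 2 trips")
  vars <- intersect(vars, names(dataset))
  xm <- rf_matrix(dataset, vars)
  scores <- lapply(mtry_grid, function(m)
    oof_scores(xm, y, folds, m, ntree, min_node, seed))
  aucs <- vapply(scores, function(s) auc(y == 1, s), 1.0)
  best <- which(aucs == max(aucs))[1]  # tie -> smaller mtry (grid is ascending)
  set.seed(derive_seed(seed, paste0("final", mtry_grid[best])))
  model <- random_forest(xm, y, ntree = ntree, mtry = mtry_grid[best],
                         min_node = min_node)
  list(model = model, mtry = mtry_grid[best], auc_cv = aucs[best],
       oof = scores[[best]], auc_by_mtry = stats::setNames(aucs, mtry_grid))
}

#' Temporal transferability (year-grouped folds)
#'
#' Trips are grouped by year; years are balanced greedily into at most `k`
#' folds exactly as in [make_trip_folds()], and the pooled out-of-fold AUC
#' is returned. With a single year the metric is undefined and `NA` is
#' returned with attribute `reason`.
#'
#' @param dataset Replicate dataset rows.
#' @param mtry The (tuned) mtry to use.
#' @inheritParams tune_and_fit
#' @return `AUC_Time`, or flagged `NA` if only one year is present.
#' @export
temporal_transfer <- function(dataset, mtry, k = 10, vars = model_variables(),
                              ntree = 500, min_node = 1, seed = 1) {
  years <- sort(unique(dataset$year))
  if (length(years) < 2) {
    out <- NA_real_
    attr(out, "reason") <- "single year: temporal transferability undefined"
    return(out)
  }
  sizes <- table(dataset$year)
  fold_by_year <- greedy_folds(stats::setNames(as.numeric(sizes), names(sizes)), k)
  folds <- unname(fold_by_year[as.character(dataset$year)])
  vars <- intersect(vars, names(dataset))
  y <- as.integer(dataset$label == "presence")
  s <- oof_scores(rf_matrix(dataset, vars), y, folds, mtry, ntree, min_node,
                  derive_seed(seed, "time"))
  auc(y == 1, s)
}

#' Spatial transferability of an ensemble to another complex's data
#'
#' Mean over the ensemble's replicate models of the AUC of their predictions
#' on the target dataset (model transferability). Predicting a dataset drawn
#' from the same complex gives a resubstitution-flavoured diagnostic, not an
#' independent test.
#'
#' @param ensemble A `model_ensemble`.
#' @param dataset Rows of the target complex (with `label` and covariates).
#' @return Mean AUC across replicate models.
#' @export
spatial_transfer <- function(ensemble, dataset) {
  y <- dataset$label == "presence"
  mean(vapply(ensemble$models, function(m) auc(y, predict(m, dataset)), 1.0))
}

#' Scale Gini importances to 0-100
#'
#' Linear rescale per model so the most important variable scores 100 and
#' the least important 0; if all raw importances are equal the scaling is
#' ill-posed and every variable gets 50.
#'
#' @param raw Named numeric vector of raw Gini importances (or a `cpf_rf`).
#' @return Named numeric vector on [0, 100].
#' @export
importance_scaled <- function(raw) {
  if (inherits(raw, "cpf_rf")) raw <- raw$importance
  rng <- range(raw)
  if (diff(rng) == 0) return(stats::setNames(rep(50, length(raw)), names(raw)))
  (raw - rng[1]) / diff(rng) * 100
}

#' Partial dependence of predicted occurrence on one covariate
#'
#' `PD(v)` is the mean predicted presence probability over the dataset rows
#' with the covariate forced to `v`, evaluated on a quantile-spaced grid.
#' For ensembles, per-replicate curves are returned together with a
#' loess-smoothed mean curve.
#'
#' @param model A `cpf_rf` or `model_ensemble`.
#' @param dataset Rows providing the background distribution.
#' @param variable Covariate name.
#' @param n_grid Number of quantile-spaced evaluation points (default 50).
#' @param span Loess span for the smoothed ensemble curve (default 0.75).
#' @return data.frame with `value`, `pd` (and per-replicate columns plus
#'   `pd_smooth` for ensembles).
#' @export
partial_dependence <- function(model, dataset, variable, n_grid = 50,
                               span = 0.75) {
  grid <- unique(stats::quantile(as.data.frame(dataset)[[variable]],
                                 probs = seq(0, 1, length.out = n_grid),
                                 names = FALSE, type = 7))
  d <- as.data.frame(dataset)
  pd_one <- function(m) vapply(grid, function(v) {
    d[[variable]] <- v
    mean(predict(m, d))
  }, 1.0)
  if (inherits(model, "model_ensemble")) {
    mat <- vapply(model$models, pd_one, numeric(length(grid)))
    pd <- rowMeans(mat)
    sm <- if (length(grid) >= 10)
      stats::predict(stats::loess(pd ~ grid, span = span), grid) else pd
    out <- data.frame(value = grid, pd = pd, pd_smooth = sm)
    out <- cbind(out, stats::setNames(as.data.frame(mat),
                                      paste0("rep", seq_len(ncol(mat)))))
    return(out)
  }
  data.frame(value = grid, pd = pd_one(model))
}

#' Fit a replicate random-forest ensemble for one habitat
#'
#' Screens covariates for collinearity on the pooled replicate rows, then for
#' each replicate dataset builds trip-grouped folds, tunes mtry over the
#' grid, fits the final forest, and computes the temporal-transfer AUC.
#'
#' @param replicates List of replicate datasets (one habitat), as produced by
#'   [build_replicates()].
#' @param habitat Habitat label ("shelf"/"basin").
#' @param scope Complex scope label (default "all" = pooled).
#' @param mtry_grid,k,ntree,min_node Tuning/forest settings (paper defaults).
#' @param threshold Collinearity threshold (default 0.7).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A `model_ensemble`: models, chosen mtry and AUCs per replicate,
#'   scaled importance matrix, retained variable list, screening report.
#' @export
fit_ensemble <- function(replicates, habitat, scope = "all",
                         mtry_grid = c(2, 3, 4), k = 10, ntree = 500,
                         min_node = 1, threshold = 0.7, seed = 1) {
  replicates <- Filter(function(d) NROW(d) > 0, replicates)
  if (length(replicates) == 0) stop("no replicate data for habitat ", habitat)
  pooled <- data.table::rbindlist(replicates)
  screen <- collinearity_screen(pooled, threshold = threshold)
  vars <- screen$retained
  fits <- lapply(seq_along(replicates), function(r) {
    d <- replicates[[r]]
    folds <- make_trip_folds(d, k)
    fit <- tune_and_fit(d, folds, mtry_grid = mtry_grid, vars = vars,
                        ntree = ntree, min_node = min_node,
                        seed = derive_seed(seed, paste0("ens", r)))
    fit$auc_time <- temporal_transfer(d, fit$mtry, k = k, vars = vars,
                                      ntree = ntree, min_node = min_node,
                                      seed = derive_seed(seed, paste0("ens", r)))
    fit
  })
  imp <- t(vapply(fits, function(f) importance_scaled(f$model),
                  numeric(length(vars))))
  colnames(imp) <- vars
  structure(list(habitat = habitat, scope = scope,
                 models = lapply(fits, `[[`, "model"),
                 mtry = vapply(fits, `[[`, 1.0, "mtry"),
                 auc_cv = vapply(fits, `[[`, 1.0, "auc_cv"),
                 auc_time = vapply(fits, function(f) as.numeric(f$auc_time), 1.0),
                 importance = imp, variables = vars, screening = screen,
                 datasets = replicates, ntree = ntree, min_node = min_node),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("model_ensemble (%s, %s): %d replicates, AUC_CV %.3f +/- %.3f\n",
              x$scope, x$habitat, length(x$models), mean(x$auc_cv),
              stats::sd(x$auc_cv)))
  invisible(x)
}

#' @param object A `model_ensemble`.
#' @param newdata Covariate rows.
#' @param ... Unused.
#' @return Mean predicted probability over replicate models.
#' @rdname fit_ensemble
#' @export
predict.model_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$models, function(m) predict(m, newdata),
                  numeric(NROW(newdata)))
  if (NROW(newdata) == 1L) mean(preds) else rowMeans(preds)
}

#' Ensemble metrics table (one row per ensemble)
#'
#' Mirrors the usual model-performance summary: sample sizes, AUC_CV
#' mean/sd, AUC_Time mean/sd, and the range of cross-complex AUCs if
#' supplied.
#'
#' @param ensembles List of `model_ensemble` objects.
#' @param auc_space Optional named numeric list per ensemble of
#'   cross-complex AUCs.
#' @return data.frame.
#' @export
ensemble_metrics <- function(ensembles, auc_space = NULL) {
  rows <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    pooled <- data.table::rbindlist(e$datasets)
    sp <- if (!is.null(auc_space)) auc_space[[i]] else NA_real_
    data.frame(scope = e$scope, habitat = e$habitat,
               n_seal = length(unique(pooled$animal_id)),
               n_trip = length(unique(pooled$trip_id)),
               n_year = length(unique(pooled$year)),
               auc_cv_mean = mean(e$auc_cv), auc_cv_sd = stats::sd(e$auc_cv),
               auc_time_mean = mean(e$auc_time, na.rm = TRUE),
               auc_time_sd = stats::sd(e$auc_time, na.rm = TRUE),
               auc_space_min = suppressWarnings(min(sp, na.rm = TRUE)),
               auc_space_max = suppressWarnings(max(sp, na.rm = TRUE)))
  })
  do.call(rbind, rows)
}
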