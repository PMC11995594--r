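# Collinearity screening, folds, AUC, tuning, transferability, importance,
# partial dependence, and the compiled forest itself.

test_that("AUC equals the pairwise-comparison oracle", {
  auc_brute <- function(y, s) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.1, 0.2)), 1.0)
  expect_equal(auc(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4)), 0.5)
  set.seed(20)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 30, TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), 30, TRUE)  # ties likely
    expect_identical(auc(y, s), auc_brute(y, s))
  }
  expect_error(auc(rep(TRUE, 3), 1:3), "both classes")
})

test_that("collinearity screen drops the static variable of a hot pair", {
  set.seed(5)
  n <- 400
  bathy <- runif(n, 200, 1500)
  d <- data.frame(
    bathymetry = bathy,
    temp_bottom = 2 + 0.002 * bathy + rnorm(n, 0, 0.35),  # r ~ 0.9
    temp_surface = rnorm(n), phl = rnorm(n), phl_avg = rnorm(n),
    ncao_ncas = rnorm(n), eup = rnorm(n))
  expect_gt(abs(cor(d$bathymetry, d$temp_bottom)), 0.85)
  sc <- collinearity_screen(d)
  expect_true("bathymetry" %in% sc$dropped)
  expect_false("temp_bottom" %in% sc$dropped)
  expect_identical(sc$retained, setdiff(model_variables(), "bathymetry"))
  # no hot pair: identity
  d2 <- d; d2$temp_bottom <- rnorm(n)
  expect_identical(collinearity_screen(d2)$retained, model_variables())
  # exact linear dependence flagged at r = 1
  d3 <- d2; d3$eup <- 2 * d3$phl + 1
  sc3 <- collinearity_screen(d3)
  expect_equal(abs(sc3$flagged$r[1]), 1.0, tolerance = 1e-12)
  expect_true("eup" %in% sc3$dropped)  # later of two dynamic variables
})

test_that("trip-grouped folds never split a trip and balance greedily", {
  d <- data.frame(trip_id = rep(sprintf("T%02d", 1:10), each = 20))
  f <- make_trip_folds(d, 10)
  expect_equal(length(unique(f)), 10)
  expect_true(all(table(f) == 20))     # one trip per fold
  # uneven trips: no split, bounded imbalance
  sizes <- c(50, 40, 30, 22, 18, 11, 7, 5)
  d2 <- data.frame(trip_id = rep(sprintf("T%d", seq_along(sizes)), times = sizes))
  f2 <- make_trip_folds(d2, 4)
  per_trip <- tapply(f2, d2$trip_id, function(x) length(unique(x)))
  expect_true(all(per_trip == 1))
  tot <- tapply(rep(1, nrow(d2)), f2, sum)
  expect_lte(max(tot) - min(tot), max(sizes))
  # fewer trips than k: k reduced
  expect_lte(length(unique(make_trip_folds(d2, 20))), length(sizes))
})

test_that("tuning finds the separable structure and is reproducible", {
  d <- toy_model_data(beta = 50)        # x1 separates almost perfectly
  folds <- make_trip_folds(d, 5)
  fit <- tune_and_fit(d, folds, mtry_grid = c(1, 2), vars = c("x1", "x2", "x3"),
                      ntree = 150, seed = 3)
  expect_gte(fit$auc_cv, 0.99)
  fit2 <- tune_and_fit(d, folds, mtry_grid = c(1, 2), vars = c("x1", "x2", "x3"),
                       ntree = 150, seed = 3)
  expect_identical(fit$mtry, fit2$mtry)
  expect_identical(fit$oof, fit2$oof)
  # single-label data is a hard error
  d1 <- d; d1$label <- "presence"
  expect_error(tune_and_fit(d1, folds), "both labels")
})

test_that("permuted labels give chance-level pooled out-of-fold AUC", {
  d <- toy_model_data(n_trips = 12, rows_per_trip = 40, beta = 3, seed = 9)
  set.seed(10)
  d$label <- sample(d$label)            # break the signal
  folds <- make_trip_folds(d, 10)
  fit <- tune_and_fit(d, folds, mtry_grid = 2, vars = c("x1", "x2", "x3"),
                      ntree = 300, seed = 4)
  expect_gte(fit$auc_cv, 0.4)
  expect_lte(fit$auc_cv, 0.6)
})

test_that("out-of-fold predictions depend only on other folds' rows", {
  d <- toy_model_data(n_trips = 6, rows_per_trip = 25, seed = 3)
  folds <- make_trip_folds(d, 3)
  xm <- cpfhabitat:::rf_matrix(d, c("x1", "x2", "x3"))
  y <- as.integer(d$label == "presence")
  oof <- cpfhabitat:::oof_scores(xm, y, folds, mtry = 2, ntree = 100,
                                 min_node = 1, seed = 11)
  # oracle: retrain on the complement of fold 1 with the same derived seed
  hold <- folds == 1
  set.seed(cpfhabitat:::derive_seed(11, "fold1mtry2"))
  m <- random_forest(xm[!hold, ], y[!hold], ntree = 100, mtry = 2)
  expect_identical(oof[hold], as.numeric(predict(m, xm[hold, ])))
})

test_that("temporal transfer is near chance when the signal does not cross years", {
  set.seed(21)
  n <- 200
  mk_year <- function(year, informative) {
    lab <- rep(c("presence", "absence"), n / 2)
    x2 <- if (informative) (lab == "presence") * 2 + rnorm(n, 0, 0.5)
          else rnorm(n, 0, 0.5)
    data.table::data.table(
      trip_id = sprintf("%d_T%d", year, rep(1:10, each = n / 10)),
      year = year, x1 = year - 2001 + rnorm(n, 0, 0.1), x2 = x2, label = lab)
  }
  d <- rbind(mk_year(2001, TRUE), mk_year(2002, FALSE))
  folds <- make_trip_folds(d, 10)
  fit <- tune_and_fit(d, folds, mtry_grid = 1, vars = c("x1", "x2"),
                      ntree = 200, seed = 5)
  at <- temporal_transfer(d, mtry = 1, vars = c("x1", "x2"), ntree = 200, seed = 5)
  expect_gt(fit$auc_cv, 0.65)           # mixed-year CV sees the signal
  expect_lt(abs(at - 0.5), 0.12)        # year-held-out transfer is chance
  # single year: flagged absence
  one <- d[d$year == 2001, ]
  res <- temporal_transfer(one, mtry = 1)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "single year")
})

test_that("spatial transfer inverts under opposite preferences", {
  set.seed(31)
  mk <- function(sign, n = 300) {
    x1 <- rnorm(n)
    lab <- ifelse(stats::runif(n) < stats::plogis(sign * 3 * x1),
                  "presence", "absence")
    data.table::data.table(trip_id = rep(sprintf("s%d_T%d", sign, 1:6),
                                         length.out = n),
                           x1 = x1, x2 = rnorm(n), label = lab)
  }
  dA <- mk(+1); dB <- mk(-1); dA2 <- mk(+1)
  folds <- make_trip_folds(dA, 5)
  fit <- tune_and_fit(dA, folds, mtry_grid = 1, vars = c("x1", "x2"),
                      ntree = 200, seed = 6)
  ens <- structure(list(models = list(fit$model), habitat = "shelf",
                        scope = "A"), class = "model_ensemble")
  expect_lt(spatial_transfer(ens, dB), 0.5)   # opposite world
  expect_gt(spatial_transfer(ens, dA2), 0.75) # exchangeable world transfers
  # A = B equals mean resubstitution AUC by definition
  expect_equal(spatial_transfer(ens, dA),
               auc(dA$label == "presence", predict(fit$model, dA)))
})

test_that("importance scaling maps raw Gini scores onto 0-100", {
  expect_equal(unname(importance_scaled(c(a = 2, b = 5, c = 8))),
               c(0, 50, 100))
  expect_equal(unname(importance_scaled(c(a = 3, b = 3))), c(50, 50))
  # a pure-noise covariate ranks far below a determining one
  d <- toy_model_data(beta = 50, seed = 13)
  m <- random_forest(d[, c("x1", "x2", "x3")], d$label == "presence",
                     ntree = 200, mtry = 1, seed = 2)
  sc <- importance_scaled(m)
  expect_equal(unname(sc["x1"]), 100)
  expect_lt(sc["x2"], 20)
})

test_that("partial dependence is flat for an ignored covariate and bounded", {
  d <- toy_model_data(beta = 50, seed = 17)
  # mtry = p: the dominant covariate is always available, so the noise
  # covariates are never split on and their marginal effect is flat
  m <- random_forest(d[, c("x1", "x2", "x3")], d$label == "presence",
                     ntree = 300, mtry = 3, seed = 3)
  pd2 <- partial_dependence(m, d, "x2")
  expect_true(all(pd2$pd >= 0 & pd2$pd <= 1))
  expect_lt(max(pd2$pd) - min(pd2$pd), 0.04)
  pd1 <- partial_dependence(m, d, "x1")
  expect_gt(max(pd1$pd) - min(pd1$pd), 0.5)  # the real driver moves the response
})

test_that("the forest is deterministic under a seed and separates cleanly", {
  set.seed(1)
  x <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] > 0)
  m1 <- random_forest(x, y, ntree = 100, mtry = 1, seed = 5)
  m2 <- random_forest(x, y, ntree = 100, mtry = 1, seed = 5)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_gte(auc(y == 1, predict(m1, x)), 0.99)
  p <- predict(m1, matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b"))))
  expect_true(all(p >= 0 & p <= 1))
})
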