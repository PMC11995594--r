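## ExDet extrapolation diagnostics: classify target covariate vectors
## relative to a reference sample as analogue, univariate (outside some
## variable's reference range) or combinatorial (inside all ranges but a
## novel combination), with the most-influential covariate per point.

#' Extrapolation detection (ExDet)
#'
#' For each target row, `NT1 = sum_j min(0, min(x_j - min_j, max_j - x_j)) /
#' (max_j - min_j)` measures univariate novelty (0 = inside every reference
#' range, negative = outside). For rows with `NT1 = 0`,
#' `NT2 = D2(x) / max_ref D2` is the Mahalanobis distance to the reference
#' mean (reference covariance) normalized by the largest reference
#' Mahalanobis distance; `NT2 > 1` marks combinatorial novelty.
#' Classes: `univariate` iff `NT1 < 0`; `combinatorial` iff `NT1 = 0` and
#' `NT2 > 1`; otherwise `analogue`. The most-influential covariate (MIC) is
#' the variable with the most negative NT1 term (univariate) or the variable
#' whose removal most reduces D2 (combinatorial, leave-one-out).
#'
#' A singular reference covariance is ridge-regularized with
#' `eps = 1e-8 * trace / p` (logged via a message). A constant reference
#' column contributes 0 to NT1 when the target equals the constant and
#' `-Inf` (class univariate) otherwise.
#'
#' @param reference n x p matrix/data.frame of reference covariate rows
#'   (n > p + 1).
#' @param targets m x p matrix/data.frame with the same columns.
#' @return An `exdet_result` data.frame: `NT1`, `NT2`, `class`, `mic`.
#' @export
exdet <- function(reference, targets) {
  ref <- as.matrix(reference); tar <- as.matrix(targets)
  storage.mode(ref) <- "double"; storage.mode(tar) <- "double"
  p <- ncol(ref)
  if (nrow(ref) <= p + 1) stop("need n > p + 1 reference rows")
  vars <- colnames(ref)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  mins <- apply(ref, 2, min); maxs <- apply(ref, 2, max)
  rng <- maxs - mins
  const <- rng == 0

  ## per-variable NT1 terms
  terms <- matrix(0, nrow(tar), p)
  for (j in seq_len(p)) {
    if (const[j]) {
      terms[, j] <- ifelse(tar[, j] == mins[j], 0, -Inf)
    } else {
      terms[, j] <- pmin(0, pmin(tar[, j] - mins[j], maxs[j] - tar[, j])) / rng[j]
    }
  }
  if (any(const)) message("constant reference column(s): ",
                          paste(vars[const], collapse = ","))
  NT1 <- rowSums(terms)

  ## Mahalanobis machinery on non-constant columns
  use <- which(!const)
  mu <- colMeans(ref[, use, drop = FALSE])
  S <- stats::cov(ref[, use, drop = FALSE])
  if (rcond_safe(S) < 1e-12) {
    eps <- 1e-8 * sum(diag(S)) / length(use)
    S <- S + diag(eps, length(use))
    message("singular reference covariance; ridge eps = ", format(eps))
  }
  Sinv <- solve(S)
  d2_ref <- stats::mahalanobis(ref[, use, drop = FALSE], mu, Sinv, inverted = TRUE)
  d2_max <- max(d2_ref)
  d2_tar <- stats::mahalanobis(tar[, use, drop = FALSE], mu, Sinv, inverted = TRUE)
  NT2 <- d2_tar / d2_max

  cls <- ifelse(NT1 < 0, "univariate",
                ifelse(NT2 > 1, "combinatorial", "analogue"))
  mic <- rep(NA_character_, nrow(tar))
  uni <- which(cls == "univariate")
  if (length(uni)) mic[uni] <- vars[apply(terms[uni, , drop = FALSE], 1, which.min)]
  comb <- which(cls == "combinatorial")
  for (i in comb) {
    drop_red <- vapply(seq_along(use), function(k) {
      keep <- use[-k]
      mu_k <- colMeans(ref[, keep, drop = FALSE])
      S_k <- stats::cov(ref[, keep, drop = FALSE])
      if (rcond_safe(S_k) < 1e-12)
        S_k <- S_k + diag(1e-8 * sum(diag(S_k)) / length(keep), length(keep))
      d2_tar[i] - stats::mahalanobis(tar[i, keep, drop = FALSE], mu_k,
                                     solve(S_k), inverted = TRUE)
    }, 1.0)
    mic[i] <- vars[use[which.max(drop_red)]]
  }
  structure(data.frame(NT1 = NT1, NT2 = ifelse(NT1 < 0, NA_real_, NT2),
                       class = cls, mic = mic, stringsAsFactors = FALSE),
            class = c("exdet_result", "data.frame"))
}

rcond_safe <- function(S) {
  if (length(S) == 1) return(as.numeric(S != 0))
  tryCatch(rcond(S), error = function(e) 0)
}

#' Summarize ExDet classes over cells and weeks
#'
#' Pools per-week ExDet results and reports the fraction of (cell, week)
#' instances in each class plus a MIC frequency table. Variables whose
#' extrapolation is an artifact (e.g. biomass values near zero) can be
#' excluded from the class summary.
#'
#' @param results List of `exdet_result` objects (e.g. one per week).
#' @param scenario Scenario label attached to the output.
#' @param exclude_vars MIC variables to drop from the summary (their rows are
#'   reclassified as analogue for the fractions).
#' @return List: `scenario`, `fractions` (named: analogue, univariate,
#'   combinatorial; sums to 1), `mic_table`, `n`.
#' @export
exdet_summary <- function(results, scenario = "scenario",
                          exclude_vars = character(0)) {
  all <- do.call(rbind, lapply(results, as.data.frame))
  cls <- all$class
  if (length(exclude_vars))
    cls[!is.na(all$mic) & all$mic %in% exclude_vars] <- "analogue"
  lev <- c("analogue", "univariate", "combinatorial")
  fr <- as.numeric(table(factor(cls, levels = lev))) / length(cls)
  list(scenario = scenario,
       fractions = stats::setNames(fr, lev),
       mic_table = table(all$mic[!is.na(all$mic)]),
       n = length(cls))
}
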