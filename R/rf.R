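## R-side wrapper around the compiled CART forest (see src/rf.cpp).

#' Random-forest classifier (bagged CART, Gini splitting)
#'
#' Fits a probability forest for a binary outcome: each tree is grown on a
#' bootstrap sample, candidate split variables are subsampled (`mtry`) at
#' every node, nodes are split by maximum Gini impurity decrease until pure
#' or smaller than `min_node`, and predicted probabilities are terminal-node
#' class fractions averaged over trees. Gini importance is the total
#' impurity decrease per variable (bootstrap-size normalized, averaged over
#' trees). Reproducible under `set.seed()` / the `seed` argument.
#'
#' @param x data.frame or matrix of numeric predictors.
#' @param y Binary outcome: logical, 0/1, or factor whose second level is the
#'   positive class.
#' @param ntree Number of trees (default 500).
#' @param mtry Variables sampled as split candidates at each node.
#' @param min_node Minimum terminal node size (default 1).
#' @param seed Optional integer seed (`NULL` = use current RNG state).
#' @return A `cpf_rf` object.
#' @export
random_forest <- function(x, y, ntree = 500, mtry = 2, min_node = 1, seed = NULL) {
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (is.null(colnames(xm))) colnames(xm) <- paste0("V", seq_len(ncol(xm)))
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  fit <- rf_fit_cpp(xm, y, as.integer(ntree), as.integer(mtry), as.integer(min_node))
  structure(list(trees = fit$trees,
                 importance = stats::setNames(fit$importance, colnames(xm)),
                 variables = colnames(xm), ntree = ntree, mtry = mtry,
                 min_node = min_node),
            class = "cpf_rf")
}

#' @param object A `cpf_rf` model.
#' @param newdata data.frame/matrix containing the model's variables.
#' @param ... Unused.
#' @return Numeric vector of presence probabilities in [0, 1].
#' @rdname random_forest
#' @export
predict.cpf_rf <- function(object, newdata, ...) {
  xm <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  storage.mode(xm) <- "double"
  rf_predict_cpp(object$trees, xm)
}

#' @export
print.cpf_rf <- function(x, ...) {
  cat(sprintf("cpf_rf: %d trees, mtry %d, min node %d, %d variables\n",
              x$ntree, x$mtry, x$min_node, length(x$variables)))
  invisible(x)
}
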