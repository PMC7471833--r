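#' Fit the built-in randomized-tree ensemble
#'
#' A bagged CART ensemble (Gini splits, random feature subsets at every
#' node), deterministic given the seed. It is the package's reference
#' ensemble classifier and the model whose Shapley values the stability
#' selector aggregates; its tree structure is exposed so the exact
#' interventional tree explainer can be used instead of Monte-Carlo
#' sampling.
#'
#' @param x Numeric matrix, instances x features.
#' @param y Logical or 0/1 vector: positive-class membership.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param max_depth Maximum tree depth (default 12).
#' @param min_split Minimum node size to attempt a split (default 5).
#' @param seed Integer seed.
#' @return An object of class `tree_ensemble`.
#' @export
tree_ensemble <- function(x, y, n_trees = 100, mtry = NULL, max_depth = 12,
                          min_split = 5, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  p <- ncol(x)
  mtry <- as.integer(mtry %||% max(1L, floor(sqrt(p))))
  trees <- .cpp_forest_fit(x, y, as.integer(n_trees),
                           min(mtry, p), as.integer(max_depth),
                           as.integer(min_split), as.integer(seed))
  structure(list(trees = trees, n_features = p,
                 feature_names = colnames(x), n_trees = n_trees,
                 seed = seed),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("<tree_ensemble> %d trees over %d features\n",
              x$n_trees, x$n_features))
  invisible(x)
}

#' Predict positive-class probabilities from a tree ensemble
#'
#' @param object A `tree_ensemble`.
#' @param newdata Numeric matrix, instances x features, same feature order
#'   as at fit time.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$n_features)
  .cpp_forest_predict(object$trees, newdata)
}

#' Turn a fitted model into a black-box scoring function
#'
#' The scoring contract consumed by the Shapley module: a deterministic
#' function mapping a matrix of instances (rows) to one real score per
#' instance — for classifiers, the positive-class probability.
#'
#' @param fit A fitted model (`tree_ensemble` or anything with a matching
#'   `predict` method returning scores).
#' @return A function `(matrix) -> numeric`.
#' @export
model_function <- function(fit) {
  force(fit)
  function(x) predict(fit, x)
}
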