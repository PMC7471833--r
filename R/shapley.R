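#' @section Coalition value convention:
#' The coalition value `f_x(S)` is the marginal (interventional)
#' expectation over a fixed background sample: features outside `S` are
#' replaced by background values and the model scores are averaged. Under
#' this convention `f_x(all) = f(x)` and `f_x(empty) = mean model score
#' over the background`, which makes the exact oracle well defined and the
#' additive decomposition checkable to floating tolerance.
#' @name shapley
#' @keywords internal
NULL

coalition_value <- function(model, background, instance, members) {
  h <- background
  for (j in members) h[, j] <- instance[j]
  mean(model(h))
}

#' Exact Shapley values by subset enumeration
#'
#' Computes, for every feature i,
#' `phi_i = sum_{S subset of features \ {i}} |S|! (M - |S| - 1)! / M! *
#' (f_x(S + i) - f_x(S))`
#' by enumerating all `2^M` coalitions. Cost is exponential in the number
#' of features, so a hard cap applies; use [estimate_shapley()] beyond it.
#'
#' @param model A scoring function (see [model_function()]).
#' @param background Numeric matrix of background rows (samples x
#'   features) defining the marginal expectation.
#' @param instance Numeric vector, the instance to explain.
#' @param cap Maximum number of features (default 15).
#' @return A list with `phi` (numeric vector), `phi0` (base value) and
#'   `fx` (the model score of the instance).
#' @export
exact_shapley <- function(model, background, instance, cap = 15) {
  m <- length(instance)
  if (m > cap) {
    stop(sprintf(paste0("exact enumeration over %d features exceeds the cap",
                        " of %d; use estimate_shapley()"), m, cap),
         call. = FALSE)
  }
  stopifnot(is.matrix(background), ncol(background) == m)
  n_mask <- bitwShiftL(1L, m)
  sizes <- vapply(seq_len(n_mask) - 1L, function(mask)
    sum(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L), integer(1L))
  v <- numeric(n_mask)
  for (mask in seq_len(n_mask) - 1L) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    v[mask + 1L] <- coalition_value(model, background, instance, members)
  }
  # Shapley kernel weight by coalition size, via log-factorials
  wts <- exp(lfactorial(0:(m - 1L)) + lfactorial(m - 1L - (0:(m - 1L))) -
             lfactorial(m))
  phi <- numeric(m)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(seq_len(n_mask) - 1L, bit) == 0L)
    s <- sizes[without]
    phi[i] <- sum(wts[s + 1L] * (v[without + bit] - v[without]))
  }
  names(phi) <- colnames(background)
  list(phi = phi, phi0 = v[1L], fx = v[n_mask])
}

#' Monte-Carlo permutation estimate of Shapley values
#'
#' Samples random feature permutations; walking each permutation from the
#' background toward the instance yields one unbiased marginal-contribution
#' draw per feature. Deterministic given the seed; the per-feature
#' Monte-Carlo standard error is returned so agreement with the exact
#' oracle can be judged in standard-error units.
#'
#' @inheritParams exact_shapley
#' @param n_perm Permutation budget (default 200).
#' @param seed Integer seed.
#' @return A list with `phi`, `phi0`, `fx` and `se` (per-feature standard
#'   error of the estimate).
#' @export
estimate_shapley <- function(model, background, instance, n_perm = 200,
                             seed = 1) {
  m <- length(instance)
  stopifnot(is.matrix(background), ncol(background) == m, n_perm >= 1)
  nb <- nrow(background)
  draws <- matrix(NA_real_, nrow = n_perm, ncol = m)
  with_seed(substream_seed(seed, "shap-perm"), {
    for (p in seq_len(n_perm)) {
      perm <- sample.int(m)
      # hybrid block: coalition k = first k features of perm set to x
      h <- background[rep(seq_len(nb), m + 1L), , drop = FALSE]
      cur <- background
      for (k in seq_len(m)) {
        cur[, perm[k]] <- instance[perm[k]]
        rows <- (k * nb + 1L):((k + 1L) * nb)
        h[rows, ] <- cur
      }
      s <- model(h)
      vals <- vapply(0:m, function(k) mean(s[(k * nb + 1L):((k + 1L) * nb)]),
                     numeric(1L))
      draws[p, perm] <- diff(vals)
    }
  })
  phi <- colMeans(draws)
  se <- if (n_perm > 1) apply(draws, 2L, stats::sd) / sqrt(n_perm)
        else rep(Inf, m)
  names(phi) <- names(se) <- colnames(background)
  list(phi = phi, phi0 = mean(model(background)),
       fx = mean(model(matrix(instance, nrow = 1L,
                              dimnames = list(NULL, colnames(background))))),
       se = se)
}

#' Exact interventional Shapley values for a tree ensemble
#'
#' Uses the tree structure directly: for every (tree, background row) pair
#' each root-to-leaf path induces a simple coalition game whose Shapley
#' values have a closed form, so the result equals [exact_shapley()] on the
#' same model and background without exponential cost.
#'
#' @param fit A [tree_ensemble()].
#' @param background Numeric matrix, background rows x features.
#' @param instances Numeric matrix, instances to explain x features.
#' @return A list with `phi` (matrix, instances x features) and `phi0`.
#' @export
tree_shapley <- function(fit, background, instances) {
  stopifnot(inherits(fit, "tree_ensemble"), is.matrix(background),
            is.matrix(instances),
            ncol(background) == fit$n_features,
            ncol(instances) == fit$n_features)
  out <- .cpp_tree_shap(fit$trees, instances, background)
  colnames(out$phi) <- colnames(instances) %||% fit$feature_names
  rownames(out$phi) <- rownames(instances)
  out
}

#' Per-sample, per-feature Shapley matrix for a fitted model
#'
#' Explains every instance row, auto-selecting the method: the exact tree
#' evaluator when the model is a [tree_ensemble()], exact subset
#' enumeration when the feature count is within the cap, and the
#' permutation estimator otherwise. The additive decomposition
#' `phi0 + sum_i phi_i = f(x)` is re-checked per row and reported.
#'
#' @param model A [tree_ensemble()] fit or a scoring function.
#' @param background Numeric matrix of background rows.
#' @param instances Numeric matrix of instances to explain.
#' @param method `"auto"`, `"tree"`, `"exact"` or `"permutation"`.
#' @param cap Exact-enumeration feature cap (default 15).
#' @param n_perm Permutation budget for the estimator.
#' @param seed Seed for the estimator.
#' @param tol Absolute additivity tolerance for exact methods.
#' @return An object of class `shap_matrix`: list with `values`
#'   (instances x features), `phi0`, `feature_ids`, `sample_ids`,
#'   `method`, `additivity_dev` and `additivity_ok`.
#' @export
shap_matrix <- function(model, background, instances,
                        method = c("auto", "tree", "exact", "permutation"),
                        cap = 15, n_perm = 200, seed = 1, tol = 1e-8) {
  method <- match.arg(method)
  is_tree <- inherits(model, "tree_ensemble")
  m <- ncol(instances)
  if (method == "auto") {
    method <- if (is_tree) "tree"
              else if (m <= cap) "exact"
              else "permutation"
  }
  if (method == "tree" && !is_tree) {
    stop("method 'tree' requires a tree_ensemble model", call. = FALSE)
  }
  fn <- if (is_tree) model_function(model) else model
  if (method == "tree") {
    ts <- tree_shapley(model, background, instances)
    phi <- ts$phi
    phi0 <- ts$phi0
    se <- NULL
  } else {
    phi <- matrix(NA_real_, nrow = nrow(instances), ncol = m)
    se <- matrix(NA_real_, nrow = nrow(instances), ncol = m)
    phi0 <- NA_real_
    for (i in seq_len(nrow(instances))) {
      res <- if (method == "exact") {
        exact_shapley(fn, background, instances[i, ], cap = cap)
      } else {
        estimate_shapley(fn, background, instances[i, ], n_perm = n_perm,
                         seed = substream_seed(seed, paste0("row", i)))
      }
      phi[i, ] <- res$phi
      if (method == "permutation") se[i, ] <- res$se
      phi0 <- res$phi0
    }
    if (method != "permutation") se <- NULL
  }
  fx <- fn(instances)
  dev <- abs(phi0 + rowSums(phi) - fx)
  row_tol <- if (method == "permutation") {
    # sampled rows are judged at 3 standard errors of the row sum
    3 * sqrt(rowSums(se^2)) + tol
  } else {
    rep(tol, length(dev))
  }
  ok <- dev <= row_tol
  if (!all(ok)) {
    warning(sprintf("additivity violated for %d of %d rows (max dev %.3g)",
                    sum(!ok), length(ok), max(dev)), call. = FALSE)
  }
  structure(list(values = phi, phi0 = phi0,
                 feature_ids = colnames(instances) %||%
                   paste0("f", seq_len(m)),
                 sample_ids = rownames(instances) %||%
                   paste0("x", seq_len(nrow(instances))),
                 method = method, additivity_dev = dev,
                 additivity_ok = all(ok)),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf(
    "<shap_matrix> %d samples x %d features (%s), phi0 = %.4f, additivity %s\n",
    nrow(x$values), ncol(x$values), x$method, x$phi0,
    if (x$additivity_ok) "ok" else "VIOLATED"))
  invisible(x)
}

#' Serialize a Shapley matrix as tab-delimited text
#'
#' One row per sample, one column per feature, preceded by a single
#' comment line `# phi0 <value>` holding the base value.
#'
#' @param shap A `shap_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_shap_matrix <- function(shap, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# phi0\t%.17g", shap$phi0), con)
  writeLines(paste(c("sample_id", shap$feature_ids), collapse = "\t"), con)
  for (i in seq_len(nrow(shap$values))) {
    writeLines(paste(c(shap$sample_ids[i],
                       format(shap$values[i, ], digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
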