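#' Per-fold feature importance from a Shapley matrix
#'
#' The fold importance of feature y is the sum of absolute Shapley values
#' over the fold's training samples: signs never cancel, so a feature that
#' pushes different samples in different directions still scores high.
#'
#' @param shap A [shap_matrix()].
#' @return A named nonnegative numeric vector, one entry per feature.
#' @export
fold_importance <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"), nrow(shap$values) >= 1L)
  imp <- colSums(abs(shap$values))
  names(imp) <- shap$feature_ids
  imp
}

#' Binarize a fold importance vector at its top k
#'
#' The `min(topk, Y)` largest importances are set to 1, the rest to 0.
#' Boundary ties are broken by (importance descending, feature id
#' ascending) so the indicator is deterministic.
#'
#' @param imp Named importance vector from [fold_importance()].
#' @param topk Number of features to flag.
#' @return A named 0/1 integer vector.
#' @export
binarize_topk <- function(imp, topk) {
  stopifnot(topk >= 1)
  ord <- order(-imp, names(imp))
  out <- integer(length(imp))
  names(out) <- names(imp)
  out[ord[seq_len(min(topk, length(imp)))]] <- 1L
  out
}

#' Aggregate per-fold indicators into cross-fold counts
#'
#' Element-wise sum of the K binary indicators: `F_y` is the number of
#' folds in which feature y reached the per-fold top k.
#'
#' @param indicators List of named 0/1 vectors sharing one feature space.
#' @return A named integer vector `F_y`.
#' @export
aggregate_folds <- function(indicators) {
  stopifnot(is.list(indicators), length(indicators) >= 1L)
  ref <- names(indicators[[1L]])
  for (ind in indicators[-1L]) {
    if (!identical(names(ind), ref)) {
      stop("indicators do not share the same feature space", call. = FALSE)
    }
  }
  Reduce(`+`, indicators)
}

#' Select stably important features
#'
#' Keeps features whose cross-fold count strictly exceeds the threshold:
#' with K = 10 folds and the default threshold 5, a feature must reach the
#' per-fold top k in at least 6 of 10 folds (`F_y = 5` is excluded).
#'
#' @param f_counts Named integer vector from [aggregate_folds()].
#' @param threshold Count that must be strictly exceeded (default 5).
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(f_counts, threshold = 5) {
  stopifnot(threshold >= 0)
  names(f_counts)[f_counts > threshold]
}

stratified_folds <- function(labels, n_folds, seed) {
  ids <- names(labels)
  fold <- integer(length(ids))
  names(fold) <- ids
  with_seed(substream_seed(seed, "folds"), {
    for (cls in levels(labels)) {
      g <- ids[labels == cls]
      g <- sample(g)
      fold[g] <- rep_len(seq_len(n_folds), length(g))
    }
  })
  fold
}

#' Cross-fold Shapley stability selection
#'
#' The package's headline procedure. The samples are partitioned into
#' `n_folds` stratified folds; for every fold, the specified classifier is
#' fitted on the fold's training portion and a Shapley matrix is computed
#' on that same training portion (the held-out part plays no role in
#' selection). Per-fold importances are binarized at the top `topk` and
#' summed across folds; features whose count strictly exceeds `threshold`
#' are selected. Fully deterministic given the seed.
#'
#' @param block A normalized `expression_block` (single-scale or combined).
#' @param labels Named factor from [sample_labels()].
#' @param n_folds Number of cross-validation folds (default 10).
#' @param topk Per-fold top-k cutoff (default 300).
#' @param threshold Cross-fold count that must be strictly exceeded
#'   (default 5).
#' @param model_spec A [classifier_spec()]; default the randomized-tree
#'   ensemble, whose exact tree explainer is used automatically.
#' @param seed Integer seed driving folds, model fits and explainers.
#' @param background_size Background rows for the marginal expectation,
#'   subsampled from each fold's training portion (default 100).
#' @param shap_method Method forwarded to [shap_matrix()] (default
#'   `"auto"`).
#' @param n_perm Permutation budget when the estimator is used.
#' @return A list of class `stability_profile`: `selected` (feature ids),
#'   `f_counts`, `indicators` (K x Y matrix), `importances` (K x Y),
#'   `folds`, `topk`, `threshold`.
#' @export
run_stability_selection <- function(block, labels, n_folds = 10,
                                    topk = 300, threshold = 5,
                                    model_spec = classifier_spec("rforest"),
                                    seed = 1, background_size = 100,
                                    shap_method = "auto", n_perm = 200) {
  stopifnot(inherits(block, "expression_block"), n_folds >= 2)
  lab <- labels[block$sample_ids]
  if (anyNA(lab)) stop("labels missing for some samples", call. = FALSE)
  check_two_classes(lab)
  fold <- stratified_folds(lab, n_folds, seed)
  fold <- fold[block$sample_ids]

  feats <- sort(block$feature_ids)  # canonical feature order
  indicators <- vector("list", n_folds)
  importances <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    train_ids <- block$sample_ids[fold != k]
    train_lab <- lab[train_ids]
    if (length(unique(train_lab)) < 2L) {
      stop(sprintf("fold %d training portion has a single class", k),
           call. = FALSE)
    }
    x <- t(block$values[feats, train_ids, drop = FALSE])
    fit <- fit_classifier(model_spec, x, train_lab == "positive",
                          seed = substream_seed(seed, paste0("fit", k)))
    bg_rows <- if (nrow(x) > background_size) {
      with_seed(substream_seed(seed, paste0("bg", k)),
                sort(sample.int(nrow(x), background_size)))
    } else {
      seq_len(nrow(x))
    }
    mdl <- if (inherits(fit, "tree_ensemble")) fit else model_function(fit)
    shap <- shap_matrix(mdl, x[bg_rows, , drop = FALSE], x,
                        method = shap_method, n_perm = n_perm,
                        seed = substream_seed(seed, paste0("shap", k)))
    imp <- fold_importance(shap)
    importances[[k]] <- imp
    indicators[[k]] <- binarize_topk(imp, topk)
  }
  f_counts <- aggregate_folds(indicators)
  structure(list(selected = select_features(f_counts, threshold),
                 f_counts = f_counts,
                 indicators = do.call(rbind, indicators),
                 importances = do.call(rbind, importances),
                 folds = fold, n_folds = n_folds, topk = topk,
                 threshold = threshold, seed = seed),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "<stability_profile> %d folds, topk %d, threshold %d: %d of %d features selected\n",
    x$n_folds, x$topk, x$threshold, length(x$selected),
    length(x$f_counts)))
  invisible(x)
}

#' Write a stability profile as tab-delimited text
#'
#' Emits two files: `<prefix>_selected.tsv` (feature_id, block, F_y for the
#' selected set) and `<prefix>_profile.tsv` (feature_id, block, F_y and the
#' per-fold indicator columns for every feature).
#'
#' @param profile A `stability_profile`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_stability_profile <- function(profile, prefix) {
  prov <- feature_provenance(names(profile$f_counts))
  full <- data.frame(feature_id = prov$feature_id, block = prov$block,
                     f_count = unname(profile$f_counts),
                     t(profile$indicators), stringsAsFactors = FALSE,
                     check.names = FALSE)
  names(full)[-(1:3)] <- paste0("fold", seq_len(profile$n_folds))
  sel <- full[full$feature_id %in% profile$selected, 1:3]
  paths <- c(selected = paste0(prefix, "_selected.tsv"),
             profile = paste0(prefix, "_profile.tsv"))
  utils::write.table(sel, paths[["selected"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(full, paths[["profile"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
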