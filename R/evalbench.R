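#' Confusion counts for binary predictions
#'
#' @param predicted,truth Factors or character vectors over
#'   `{"positive", "negative"}`, same length and sample order.
#' @return A list of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (!length(predicted)) stop("empty prediction vector", call. = FALSE)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length", call. = FALSE)
  }
  ok <- c("positive", "negative")
  bad <- setdiff(unique(c(predicted, truth)), ok)
  if (length(bad)) stop("unknown label value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    tp = sum(predicted == "positive" & truth == "positive"),
    tn = sum(predicted == "negative" & truth == "negative"),
    fp = sum(predicted == "positive" & truth == "negative"),
    fn = sum(predicted == "negative" & truth == "positive")),
    class = "confusion_counts")
}

#' Confusion counts from raw numbers
#' @param tp,tn,fp,fn Nonnegative counts.
#' @return A `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Accuracy
#' @param c A `confusion_counts`.
#' @return `(TP + TN) / (TP + TN + FP + FN)`.
#' @export
accuracy <- function(c) {
  with(c, (tp + tn) / (tp + tn + fp + fn))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined
#' as 0 when any marginal is empty (the 0/0 case carries no information).
#'
#' @param c A `confusion_counts`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  num <- c$tp * c$tn - c$fp * c$fn
  den <- sqrt(as.numeric(c$tp + c$fp) * (c$tp + c$fn) *
              (c$tn + c$fp) * (c$tn + c$fn))
  if (den == 0) return(0)
  num / den
}

#' F1 score
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`. With no positives anywhere
#' (`TP = FP = FN = 0`) the score defaults to the vacuous-perfection
#' convention 1, configurable to 0.
#'
#' @param c A `confusion_counts`.
#' @param empty Value when `TP = FP = FN = 0` (default 1).
#' @return F1 in `[0, 1]`.
#' @export
f1 <- function(c, empty = 1) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(empty)
  2 * c$tp / den
}

#' All three metrics at once
#' @param c A `confusion_counts`.
#' @return A list with `acc`, `mcc`, `f1`.
#' @export
metric_set <- function(c) {
  list(acc = accuracy(c), mcc = mcc(c), f1 = f1(c))
}

#' Classifier specification
#'
#' A named, seeded training contract. Two reference classifiers ship
#' built-in: `"rforest"` (the randomized-tree ensemble of
#' [tree_ensemble()]) and `"ridge"` (L2-regularized logistic regression via
#' glmnet at a fixed lambda). Any other classifier can be plugged in by
#' supplying `fit_fun(x, y, seed, params)` returning an object whose
#' `predict` method yields positive-class probabilities.
#'
#' @param name Classifier name.
#' @param params Named list of hyperparameters.
#' @param seed Integer seed; fitting is deterministic given it.
#' @param fit_fun Optional custom fitting function.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("rforest", "ridge"), params = list(),
                            seed = 1, fit_fun = NULL) {
  if (is.null(fit_fun)) name <- match.arg(name)
  structure(list(name = name, params = params, seed = as.integer(seed),
                 fit_fun = fit_fun),
            class = "classifier_spec")
}

fit_classifier <- function(spec, x, y, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  seed <- seed %||% spec$seed
  p <- spec$params
  if (!is.null(spec$fit_fun)) return(spec$fit_fun(x, y, seed, p))
  switch(spec$name,
    rforest = tree_ensemble(x, y,
                            n_trees = p$n_trees %||% 100,
                            mtry = p$mtry,
                            max_depth = p$max_depth %||% 12,
                            min_split = p$min_split %||% 5,
                            seed = seed),
    ridge = {
      fit <- glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                            family = "binomial", alpha = 0,
                            lambda = p$lambda %||% 0.01,
                            standardize = FALSE)
      structure(list(glmnet = fit, lambda = p$lambda %||% 0.01),
                class = "ridge_classifier")
    },
    stop("unknown classifier: ", spec$name, call. = FALSE))
}

#' @export
predict.ridge_classifier <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$glmnet, newx = newdata,
                            s = object$lambda, type = "response"))
}

#' Fit a classifier and predict a test block
#'
#' Features are put in canonical (lexicographic) order before fitting, so
#' the result never depends on the row order of the input blocks. The
#' hard-label decision threshold on the positive-class probability is 0.5.
#'
#' @param spec A [classifier_spec()].
#' @param train_block,test_block `expression_block`s sharing one feature
#'   set.
#' @param labels Named factor covering the training samples.
#' @return A list with `predicted` (named factor over the test samples),
#'   `prob` (positive-class probabilities), `fit` and `model`
#'   (scoring function).
#' @export
fit_predict <- function(spec, train_block, labels, test_block) {
  stopifnot(inherits(train_block, "expression_block"),
            inherits(test_block, "expression_block"))
  missing_f <- setdiff(train_block$feature_ids, test_block$feature_ids)
  extra_f <- setdiff(test_block$feature_ids, train_block$feature_ids)
  if (length(missing_f) || length(extra_f)) {
    stop("feature mismatch between train and test blocks; missing: ",
         paste(missing_f, collapse = ", "), "; extra: ",
         paste(extra_f, collapse = ", "), call. = FALSE)
  }
  feats <- sort(train_block$feature_ids)
  lab <- labels[train_block$sample_ids]
  if (anyNA(lab)) stop("labels missing for some training samples",
                       call. = FALSE)
  check_two_classes(lab)
  x_train <- t(train_block$values[feats, , drop = FALSE])
  x_test <- t(test_block$values[feats, , drop = FALSE])
  fit <- fit_classifier(spec, x_train, lab == "positive")
  prob <- predict(fit, x_test)
  predicted <- factor(ifelse(prob >= 0.5, "positive", "negative"),
                      levels = c("positive", "negative"))
  names(predicted) <- test_block$sample_ids
  list(predicted = predicted, prob = prob, fit = fit,
       model = if (inherits(fit, "tree_ensemble")) fit
               else model_function(fit))
}

rank_with <- function(method, block, labels, bins, k_neighbors, seed) {
  switch(method,
    fc = rank_fold_change(block, labels),
    oner = rank_oner(block, labels, bins = bins),
    relieff = rank_relieff(block, labels, k_neighbors = k_neighbors,
                           seed = seed),
    infogain = rank_info_gain(block, labels, bins = bins),
    gainratio = rank_gain_ratio(block, labels, bins = bins),
    stop("unknown ranking method: ", method, call. = FALSE))
}

cell_key <- function(feature_type, selector, n, classifier, seed) {
  paste(feature_type, selector, n, classifier, seed, sep = "|")
}

benchmark_cell <- function(raw_blocks, labels, feature_type, selector, n,
                           spec, seed, opts) {
  split <- split_train_test(labels, opts$train_fraction, seed,
                            stratified = opts$stratified)
  prep_one <- function(raw) {
    norm <- normalize_block(raw, method = opts$normalize,
                            train_samples = split$train)
    filt <- ttest_filter(norm, labels, alpha = opts$alpha,
                         samples = split$train)
    subset_block(norm, features = filt$retained)
  }
  blocks <- switch(feature_type,
    mRNA = list(prep_one(raw_blocks$mrna)),
    miRNA = list(prep_one(raw_blocks$mirna)),
    combined = list(prep_one(raw_blocks$mrna), prep_one(raw_blocks$mirna)))
  block <- combine_blocks(blocks)
  train_lab <- labels[split$train]
  train_block <- subset_block(block, samples = split$train)
  test_block <- subset_block(block, samples = split$test)

  feats <- if (selector == "all") {
    train_block$feature_ids
  } else if (selector == "shap") {
    sel <- run_stability_selection(
      train_block, labels, n_folds = opts$n_folds,
      topk = if (is.null(n) || is.na(n)) opts$topk else n,
      threshold = opts$threshold, model_spec = opts$shap_model %||% spec,
      seed = substream_seed(seed, "shapsel"),
      background_size = opts$background_size)
    sel$selected
  } else {
    ranking <- rank_with(selector,
                         if (selector == "fc") {
                           raw_tr <- switch(feature_type,
                             mRNA = list(subset_block(raw_blocks$mrna,
                                                      samples = split$train)),
                             miRNA = list(subset_block(raw_blocks$mirna,
                                                       samples = split$train)),
                             combined = list(
                               subset_block(raw_blocks$mrna,
                                            samples = split$train),
                               subset_block(raw_blocks$mirna,
                                            samples = split$train)))
                           fc_block <- combine_blocks(raw_tr)
                           subset_block(fc_block,
                                        features = train_block$feature_ids)
                         } else {
                           train_block
                         },
                         train_lab, bins = opts$bins,
                         k_neighbors = opts$k_neighbors,
                         seed = substream_seed(seed, "rank"))
    top_n(ranking, min(n, nrow(ranking)))
  }
  if (!length(feats)) stop("selector returned an empty feature set",
                           call. = FALSE)
  fp <- fit_predict(spec, subset_block(train_block, features = feats),
                    labels, subset_block(test_block, features = feats))
  cc <- confusion(fp$predicted, labels[split$test])
  m <- metric_set(cc)
  data.frame(feature_type = feature_type, selector = selector,
             n_features = length(feats), classifier = spec$name,
             seed = seed, acc = m$acc, mcc = m$mcc, f1 = m$f1,
             status = "ok", reason = "", stringsAsFactors = FALSE)
}

#' Run the benchmark grid
#'
#' Executes the full factorial grid of feature type x selector x top-n x
#' classifier x seed on one raw dataset. Selectors, normalization and the
#' t-test filter are fitted on the training part of each seed's split
#' only. Per-cell failures are caught and recorded with their reason,
#' never silently dropped. When `cache` names a file, completed cells are
#' loaded from it and skipped, and new records are appended, making long
#' grids resumable.
#'
#' @param dataset A list with `mrna`, `mirna` (raw `expression_block`s)
#'   and `labels`, e.g. from [generate_dataset()].
#' @param grid A list with components `feature_types` (subset of
#'   `c("mRNA","miRNA","combined")`), `selectors` (subset of
#'   `c("fc","oner","relieff","infogain","gainratio","shap","all")`),
#'   `n_values` (top-n sizes for the rankers), `classifiers` (list of
#'   [classifier_spec()]), `seeds` (integer vector).
#' @param opts Pipeline options: `train_fraction` (0.8), `stratified`
#'   (FALSE), `normalize` ("log_zscore"), `alpha` (0.05), `bins` (10),
#'   `k_neighbors` (10), `n_folds` (10), `topk` (300), `threshold` (5),
#'   `background_size` (100), `shap_model` (classifier for the SHAP
#'   stage; defaults to the cell's classifier).
#' @param cache Optional path of a tab-delimited results cache.
#' @return A tidy data frame of class `benchmark_result`, one row per
#'   grid cell.
#' @export
run_benchmark <- function(dataset, grid, opts = list(), cache = NULL) {
  defaults <- list(train_fraction = 0.8, stratified = FALSE,
                   normalize = "log_zscore", alpha = 0.05, bins = 10,
                   k_neighbors = 10, n_folds = 10, topk = 300,
                   threshold = 5, background_size = 100, shap_model = NULL)
  opts <- utils::modifyList(defaults, opts)
  done <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    done <- utils::read.table(cache, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  }
  done_keys <- if (is.null(done)) character(0) else
    with(done, cell_key(feature_type, selector, n_features_requested,
                        classifier, seed))
  records <- list()
  for (ft in grid$feature_types) {
    for (sel in grid$selectors) {
      n_values <- if (sel %in% c("shap", "all")) NA_integer_
                  else grid$n_values
      for (n in n_values) {
        for (spec in grid$classifiers) {
          for (seed in grid$seeds) {
            key <- cell_key(ft, sel, n, spec$name, seed)
            if (key %in% done_keys) next
            t0 <- proc.time()[["elapsed"]]
            rec <- tryCatch(
              benchmark_cell(dataset, dataset$labels, ft, sel, n, spec,
                             seed, opts),
              error = function(e) {
                data.frame(feature_type = ft, selector = sel,
                           n_features = NA_integer_, classifier = spec$name,
                           seed = seed, acc = NA_real_, mcc = NA_real_,
                           f1 = NA_real_, status = "error",
                           reason = conditionMessage(e),
                           stringsAsFactors = FALSE)
              })
            rec$n_features_requested <- n
            message(sprintf("[benchmark] %s: %s (%.1fs)", key, rec$status,
                            proc.time()[["elapsed"]] - t0))
            records[[key]] <- rec
          }
        }
      }
    }
  }
  new <- if (length(records)) do.call(rbind, records) else NULL
  out <- rbind(done, new)
  rownames(out) <- NULL
  if (!is.null(cache) && !is.null(new)) {
    utils::write.table(out, cache, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Summarize benchmark results
#'
#' Mean and median of each metric per group, e.g. per classifier or per
#' selector. Failed cells are excluded from the aggregates but counted.
#'
#' @param results A `benchmark_result`.
#' @param by Character vector of grouping columns.
#' @return A data frame of group summaries.
#' @export
summarize_benchmark <- function(results, by = "classifier") {
  stopifnot(nrow(results) > 0)
  bad <- setdiff(by, names(results))
  if (length(bad)) stop("unknown grouping key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ok <- results[results$status == "ok", , drop = FALSE]
  groups <- interaction(ok[by], drop = TRUE, sep = "|")
  rows <- lapply(split(ok, groups), function(g) {
    cbind(g[1L, by, drop = FALSE],
          data.frame(n_cells = nrow(g),
                     mean_acc = mean(g$acc), median_acc = stats::median(g$acc),
                     mean_mcc = mean(g$mcc), median_mcc = stats::median(g$mcc),
                     mean_f1 = mean(g$f1), median_f1 = stats::median(g$f1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch t-test between two MCC (or other metric) samples
#'
#' Unequal-variance t comparison of two sets of per-seed metric values,
#' the standard way to compare model variants' score distributions.
#'
#' @param x,y Numeric metric vectors.
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
welch_metric_test <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}
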