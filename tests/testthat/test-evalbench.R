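lab_vec <- function(x) factor(x, levels = c("positive", "negative"))

test_that("confusion counts by definition and rejects bad input", {
  truth <- lab_vec(rep(c("positive", "negative"), c(5, 3)))
  cc <- confusion(truth, truth)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 5, tn = 3, fp = 0, fn = 0))
  flipped <- lab_vec(ifelse(truth == "positive", "negative", "positive"))
  cc2 <- confusion(flipped, truth)
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 3, fn = 5))
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion("maybe", "positive"), "unknown label")
})

test_that("metric formulas match the worked cell and symmetry cases", {
  cc <- confusion_counts(tp = 6, tn = 3, fp = 1, fn = 2)
  expect_equal(accuracy(cc), 0.75)
  expect_equal(f1(cc), 0.8)
  expect_equal(mcc(cc), 16 / sqrt(1120))
  perfect <- confusion_counts(4, 4, 0, 0)
  expect_equal(unlist(metric_set(perfect)), c(acc = 1, mcc = 1, f1 = 1))
  sym <- confusion_counts(5, 5, 5, 5)
  expect_equal(unlist(metric_set(sym)), c(acc = 0.5, mcc = 0, f1 = 0.5))
  # conventions: MCC 0/0 -> 0; F1 with no positives anywhere -> 1 (or 0)
  allneg <- confusion_counts(0, 7, 0, 0)
  expect_equal(mcc(allneg), 0)
  expect_equal(f1(allneg), 1)
  expect_equal(f1(allneg, empty = 0), 0)
})

test_that("metrics equal a brute-force recount on random label vectors", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    cc <- confusion(pred, truth)
    tp <- sum(pred == "positive" & truth == "positive")
    tn <- sum(pred == "negative" & truth == "negative")
    fp <- sum(pred == "positive" & truth == "negative")
    fn <- n - tp - tn - fp
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n)
    expect_equal(accuracy(cc), (tp + tn) / n)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(mcc(cc), if (den == 0) 0 else (tp * tn - fp * fn) / den)
    expect_equal(f1(cc), if (2 * tp + fp + fn == 0) 1
                         else 2 * tp / (2 * tp + fp + fn))
    # antisymmetry of MCC under prediction inversion
    flip <- ifelse(pred == "positive", "negative", "positive")
    expect_equal(mcc(confusion(flip, truth)), -mcc(cc))
  }
})

test_that("reference classifiers separate a separable toy and are deterministic", {
  set.seed(42)
  x <- rbind(matrix(rnorm(20, mean = 2, sd = 0.3), 10, 2),
             matrix(rnorm(20, mean = -2, sd = 0.3), 10, 2))
  rownames(x) <- paste0("s", 1:20)
  colnames(x) <- c("f1", "f2")
  block <- expression_block(t(x), block = "mRNA", raw = FALSE)
  lab <- toy_labels(10, 10)
  for (name in c("rforest", "ridge")) {
    spec <- classifier_spec(name, seed = 4)
    fp1 <- fit_predict(spec, block, lab, block)
    expect_equal(accuracy(confusion(fp1$predicted, lab)), 1.0)
    fp2 <- fit_predict(spec, block, lab, block)
    expect_identical(fp1$predicted, fp2$predicted)  # determinism
  }
})

test_that("fit_predict is independent of feature row order and validates alignment", {
  set.seed(43)
  d <- generate_dataset(synth_config(n_samples = 60, n_mrna = 20,
                                     n_mirna = 5, n_informative_mrna = 5,
                                     n_informative_mirna = 1, seed = 43))
  norm <- normalize_block(d$mrna)
  lab <- d$labels
  spec <- classifier_spec("rforest", params = list(n_trees = 20), seed = 1)
  shuffled <- subset_block(norm, features = rev(norm$feature_ids))
  fp1 <- fit_predict(spec, norm, lab, norm)
  fp2 <- fit_predict(spec, shuffled, lab, norm)
  expect_identical(fp1$predicted, fp2$predicted)
  expect_error(
    fit_predict(spec, norm, lab,
                subset_block(norm, features = norm$feature_ids[1:5])),
    "feature mismatch")
})

test_that("label-independent features give test MCC centred on zero", {
  mccs <- vapply(1:20, function(s) {
    d <- generate_dataset(synth_config(n_samples = 80, n_mrna = 30,
                                       n_mirna = 10,
                                       n_informative_mrna = 0,
                                       n_informative_mirna = 0,
                                       effect_size = 0,
                                       class_balance = 0.5, seed = s))
    split <- split_train_test(d$labels, 0.8, seed = s, stratified = TRUE)
    norm <- normalize_block(d$mrna, train_samples = split$train)
    spec <- classifier_spec("rforest", params = list(n_trees = 25), seed = s)
    fp <- fit_predict(spec, subset_block(norm, samples = split$train),
                      d$labels, subset_block(norm, samples = split$test))
    mcc(confusion(fp$predicted, d$labels[split$test]))
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 3 * stats::sd(mccs) / sqrt(length(mccs)) + 0.05)
})

test_that("benchmark grid runs, records failures, resumes, and summarizes", {
  d <- generate_dataset(synth_config(n_samples = 60, n_mrna = 40,
                                     n_mirna = 12, n_informative_mrna = 8,
                                     n_informative_mirna = 2, seed = 44))
  grid <- list(feature_types = c("mRNA", "combined"),
               selectors = c("fc", "infogain", "shap", "all"),
               n_values = 10,
               classifiers = list(classifier_spec("rforest",
                                                  params = list(n_trees = 15)),
                                  classifier_spec("ridge")),
               seeds = 1)
  opts <- list(stratified = TRUE, background_size = 10, n_folds = 3,
               topk = 10, threshold = 1,
               shap_model = classifier_spec("rforest",
                                            params = list(n_trees = 10,
                                                          max_depth = 4)))
  cache <- file.path(withr::local_tempdir(), "cache.tsv")
  suppressMessages(res <- run_benchmark(d, grid, opts, cache = cache))
  expect_s3_class(res, "benchmark_result")
  expect_equal(nrow(res), 2 * 4 * 2)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$mcc >= -1 & res$mcc <= 1))
  # the shap selector reports the selected-set size, not a requested n
  shap_rows <- res[res$selector == "shap", ]
  expect_true(all(shap_rows$n_features >= 1 &
                  shap_rows$n_features <= 52))
  all_rows <- res[res$selector == "all" & res$feature_type == "combined", ]
  expect_true(all(all_rows$n_features <= 52))

  # rerun from cache: no new computation, identical result
  suppressMessages(res2 <- run_benchmark(d, grid, opts, cache = cache))
  expect_equal(nrow(res2), nrow(res))

  smry <- summarize_benchmark(res, by = "classifier")
  expect_equal(nrow(smry), 2L)
  expect_true(all(c("mean_mcc", "median_mcc") %in% names(smry)))
  expect_error(summarize_benchmark(res, by = "nope"), "unknown grouping")

  # single-record summary equals the record
  one <- res[1, ]
  class(one) <- class(res)
  s1 <- summarize_benchmark(one, by = "selector")
  expect_equal(s1$mean_mcc, one$mcc)
  expect_equal(s1$median_mcc, one$mcc)

  # two records with MCC 0.4/0.6 -> mean and median 0.5
  two <- res[1:2, ]
  two$mcc <- c(0.4, 0.6)
  two$selector <- "x"
  class(two) <- class(res)
  expect_equal(summarize_benchmark(two, by = "selector")$mean_mcc, 0.5)
})

test_that("welch comparison utility returns the unequal-variance statistic", {
  set.seed(45)
  x <- rnorm(12, 0.8, 0.05)
  y <- rnorm(12, 0.7, 0.1)
  w <- welch_metric_test(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_value, ref$p.value)
})

test_that("no test-set leakage through the full preparation pipeline", {
  d <- generate_dataset(synth_config(n_samples = 80, n_mrna = 60,
                                     n_mirna = 15, n_informative_mrna = 10,
                                     n_informative_mirna = 3, seed = 46))
  split <- split_train_test(d$labels, 0.8, seed = 3, stratified = TRUE)
  scramble <- function(block) {
    out <- block
    set.seed(99)
    out$values[, split$test] <-
      out$values[sample(nrow(out$values)), sample(split$test)]
    out
  }
  run_pipe <- function(mrna_raw) {
    norm <- normalize_block(mrna_raw, train_samples = split$train)
    filt <- ttest_filter(norm, d$labels, samples = split$train)
    train <- subset_block(norm, features = filt$retained,
                          samples = split$train)
    rank <- rank_info_gain(train, d$labels)
    sel <- run_stability_selection(
      train, d$labels, n_folds = 3, topk = 10, threshold = 1,
      model_spec = classifier_spec("rforest", params = list(n_trees = 10,
                                                            max_depth = 4)),
      seed = 4, background_size = 10)
    list(center = attr(norm, "normalization")$center,
         scale = attr(norm, "normalization")$scale,
         retained = filt$retained, ranking = rank$feature_id,
         selected = sort(sel$selected))
  }
  a <- run_pipe(d$mrna)
  b <- run_pipe(scramble(d$mrna))
  expect_identical(a, b)
})
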