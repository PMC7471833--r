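# Small in-code fixtures shared across test files.

# a tiny raw expression block with explicit values
toy_block <- function(values, block = "mRNA", raw = TRUE,
                      feature_prefix = "f", sample_prefix = "s") {
  values <- as.matrix(values)
  rownames(values) <- paste0(feature_prefix, seq_len(nrow(values)))
  colnames(values) <- paste0(sample_prefix, seq_len(ncol(values)))
  expression_block(values, block = block, raw = raw)
}

toy_labels <- function(n_pos, n_neg, prefix = "s") {
  sample_labels(paste0(prefix, seq_len(n_pos + n_neg)),
                rep(c("positive", "negative"), c(n_pos, n_neg)))
}

# a random smooth model over m features: sigmoid of a linear +
# pairwise-interaction score.  Returns the scoring function together with
# the pieces needed to build dummy/symmetric variants.
random_model <- function(m, seed, dummy = NULL, symmetric_pair = NULL) {
  set.seed(seed)
  w <- rnorm(m)
  b <- rnorm(1)
  n_int <- sample(0:2, 1)
  # interactions must avoid the dummy (it has to stay irrelevant) and the
  # symmetric pair (an asymmetric interaction breaks exchangeability)
  active <- setdiff(seq_len(m), c(dummy, symmetric_pair))
  ints <- if (n_int > 0 && length(active) >= 2) {
    replicate(n_int, sample(active, 2), simplify = FALSE)
  } else {
    list()
  }
  cint <- rnorm(length(ints), sd = 0.5)
  if (!is.null(dummy)) w[dummy] <- 0
  if (!is.null(symmetric_pair)) {
    w[symmetric_pair] <- mean(w[symmetric_pair])
  }
  fn <- function(x) {
    s <- drop(x %*% w) + b
    for (k in seq_along(ints)) {
      s <- s + cint[k] * x[, ints[[k]][1L]] * x[, ints[[k]][2L]]
    }
    stats::plogis(s)
  }
  list(fn = fn, w = w, b = b)
}

random_background <- function(m, n = 8, seed = 1, symmetric_pair = NULL) {
  set.seed(seed + 1000)
  bg <- matrix(rnorm(n * m), n, m)
  if (!is.null(symmetric_pair)) {
    bg[, symmetric_pair[2L]] <- bg[, symmetric_pair[1L]]
  }
  colnames(bg) <- paste0("f", seq_len(m))
  bg
}

# standard synthetic pipeline: normalize both blocks on training samples,
# filter on training samples, return combined block plus split
prep_pipeline <- function(dataset, seed, alpha = 0.05, stratified = TRUE) {
  split <- split_train_test(dataset$labels, 0.8, seed,
                            stratified = stratified)
  prep <- function(raw) {
    norm <- normalize_block(raw, train_samples = split$train)
    filt <- ttest_filter(norm, dataset$labels, alpha = alpha,
                         samples = split$train)
    subset_block(norm, features = filt$retained)
  }
  list(mrna = prep(dataset$mrna), mirna = prep(dataset$mirna),
       split = split)
}

informative_ids <- function(dataset, prefixed = TRUE) {
  tr <- dataset$truth[dataset$truth$informative == 1, ]
  if (prefixed) paste0(tr$block, ":", tr$feature_id) else tr$feature_id
}
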