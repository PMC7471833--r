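#' @section Ranking conventions:
#' All rankers return a `feature_ranking`: a data frame of
#' `(feature_id, weight)` covering every input feature exactly once, sorted
#' by weight (descending) with deterministic lexicographic tie-breaking on
#' the feature id. Fold change keeps its sign so the directional top-n/2
#' rule can be applied; all other methods produce nonnegative canonical
#' weights where higher is better.
#' @name rankers
#' @keywords internal
NULL

new_ranking <- function(method, feature_ids, weights, sort_by_abs = FALSE) {
  stopifnot(length(feature_ids) == length(weights), all(is.finite(weights)))
  key <- if (sort_by_abs) abs(weights) else weights
  ord <- order(-key, feature_ids)
  structure(data.frame(feature_id = feature_ids[ord],
                       weight = weights[ord], stringsAsFactors = FALSE),
            method = method, class = c("feature_ranking", "data.frame"))
}

ranking_method <- function(ranking) attr(ranking, "method")

block_and_labels <- function(block, labels) {
  stopifnot(inherits(block, "expression_block"))
  lab <- labels[block$sample_ids]
  if (anyNA(lab)) stop("labels missing for some samples", call. = FALSE)
  check_two_classes(lab)
  lab
}

#' Rank features by log2 fold change
#'
#' Weight is `log2((mean_pos + eps) / (mean_neg + eps))` on raw-scale
#' values, with a symmetric pseudocount `eps = 1e-6 * mean(values)` guarding
#' all-zero features. Signs are preserved (positive = up-regulated in the
#' positive class); the ranking is ordered by absolute weight.
#'
#' @param block A raw-scale `expression_block`.
#' @param labels Named factor from [sample_labels()].
#' @return A `feature_ranking` with signed weights.
#' @export
rank_fold_change <- function(block, labels) {
  lab <- block_and_labels(block, labels)
  if (any(block$values < 0)) {
    stop("fold change requires raw-scale (nonnegative) values", call. = FALSE)
  }
  eps <- 1e-6 * mean(block$values)
  if (eps == 0) eps <- 1e-12
  m_pos <- rowMeans(block$values[, lab == "positive", drop = FALSE])
  m_neg <- rowMeans(block$values[, lab == "negative", drop = FALSE])
  w <- log2((m_pos + eps) / (m_neg + eps))
  new_ranking("fc", block$feature_ids, w, sort_by_abs = TRUE)
}

#' Directional top-n extraction for fold-change rankings
#'
#' Takes the `ceiling(n/2)` largest positive weights (up-regulated) and the
#' `floor(n/2)` most negative weights (down-regulated). When one direction
#' runs short the deficit is backfilled from the other direction with a
#' warning.
#'
#' @param ranking A `feature_ranking` from [rank_fold_change()].
#' @param n Number of features to select.
#' @return Character vector of feature ids.
#' @export
top_n_fold_change <- function(ranking, n) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (n < 0 || n > nrow(ranking)) {
    stop("n must be between 0 and the number of features", call. = FALSE)
  }
  if (n == 0) return(character(0))
  up <- ranking[ranking$weight > 0, , drop = FALSE]
  down <- ranking[ranking$weight <= 0, , drop = FALSE]
  up <- up[order(-up$weight, up$feature_id), , drop = FALSE]
  down <- down[order(down$weight, down$feature_id), , drop = FALSE]
  n_up <- ceiling(n / 2); n_down <- floor(n / 2)
  short <- max(0, n_up - nrow(up)) + max(0, n_down - nrow(down))
  if (short > 0) {
    warning(sprintf(
      "a fold-change direction has fewer than %d features; backfilling %d from the other direction",
      max(n_up, n_down), short), call. = FALSE)
  }
  take_up <- min(n_up, nrow(up))
  take_down <- min(n_down, nrow(down))
  # backfill the deficit from whichever direction has spare features
  deficit <- n - take_up - take_down
  extra_up <- min(deficit, nrow(up) - take_up)
  take_up <- take_up + extra_up
  take_down <- take_down + (deficit - extra_up)
  c(up$feature_id[seq_len(take_up)], down$feature_id[seq_len(take_down)])
}

#' Equal-frequency discretization
#'
#' Quantile-based bins; when the feature has no more distinct values than
#' requested bins, each distinct value becomes its own bin (graceful
#' collapse for near-constant features).
#'
#' @param x Numeric vector.
#' @param bins Target number of bins.
#' @return Integer bin codes in `1..n_bins_used`.
#' @keywords internal
discretize_ef <- function(x, bins) {
  ux <- sort(unique(x))
  if (length(ux) <= bins) return(match(x, ux))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Rank features by the OneR single-feature rule
#'
#' Each feature is discretized (equal-frequency bins), every bin is assigned
#' its majority class, and the weight is the resulting training accuracy
#' (1 - error rate). Bin-level ties go to the overall majority class
#' (positive on a further tie) for determinism.
#'
#' @param block An `expression_block` (normalized values recommended).
#' @param labels Named factor from [sample_labels()].
#' @param bins Number of discretization bins (default 10).
#' @return A `feature_ranking`.
#' @export
rank_oner <- function(block, labels, bins = 10) {
  lab <- block_and_labels(block, labels)
  y <- lab == "positive"
  n <- length(y)
  overall_majority <- mean(y) >= 0.5
  w <- apply(block$values, 1L, function(x) {
    b <- discretize_ef(x, bins)
    correct <- 0
    for (g in split(seq_len(n), b)) {
      npos <- sum(y[g])
      nneg <- length(g) - npos
      if (npos == nneg) {
        correct <- correct + (if (overall_majority) npos else nneg)
      } else {
        correct <- correct + max(npos, nneg)
      }
    }
    correct / n
  })
  new_ranking("oner", block$feature_ids, unname(w))
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

info_gain_weights <- function(block, labels, bins, ratio = FALSE) {
  lab <- block_and_labels(block, labels)
  y <- as.integer(lab == "positive")
  h_y <- entropy_bits(table(y))
  apply(block$values, 1L, function(x) {
    b <- discretize_ef(x, bins)
    tab <- table(b, y)
    n <- length(y)
    h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
      (sum(tab[i, ]) / n) * entropy_bits(tab[i, ])
    }, numeric(1L)))
    ig <- h_y - h_cond
    if (!ratio) return(max(ig, 0))
    h_v <- entropy_bits(rowSums(tab))
    if (h_v <= 0) 0 else max(ig, 0) / h_v
  })
}

#' Rank features by information gain
#'
#' `InfoGain(f) = H(Y) - sum_v p(v) H(Y | v)` in bits, over equal-frequency
#' discretized feature values (same scheme as [rank_oner()]).
#'
#' @inheritParams rank_oner
#' @return A `feature_ranking`.
#' @export
rank_info_gain <- function(block, labels, bins = 10) {
  w <- info_gain_weights(block, labels, bins, ratio = FALSE)
  new_ranking("infogain", block$feature_ids, unname(w))
}

#' Rank features by gain ratio
#'
#' Information gain normalized by the entropy of the discretized feature,
#' `GainRatio(f) = InfoGain(f) / H(V)`; a constant feature (`H(V) = 0`)
#' scores 0.
#'
#' @inheritParams rank_oner
#' @return A `feature_ranking`.
#' @export
rank_gain_ratio <- function(block, labels, bins = 10) {
  w <- info_gain_weights(block, labels, bins, ratio = TRUE)
  new_ranking("gainratio", block$feature_ids, unname(w))
}

#' Rank features by ReliefF
#'
#' For each anchor sample, the k nearest same-class neighbors (hits) and k
#' nearest other-class neighbors (misses) are found by Euclidean distance;
#' each feature's weight accumulates the mean feature difference to the
#' misses minus the mean difference to the hits, with differences
#' range-normalized per feature (`diff = |a - b| / (max - min)`; a constant
#' feature has diff 0 and weight exactly 0). Samples are first sorted by id
#' so the seeded anchor sampling is invariant to input sample order.
#'
#' @inheritParams rank_oner
#' @param k_neighbors Number of neighbors per class (default 10, capped at
#'   class size - 1).
#' @param m_samples Number of anchor samples; default all samples.
#' @param seed Seed for anchor sampling when `m_samples` is smaller than
#'   the sample count.
#' @return A `feature_ranking`.
#' @export
rank_relieff <- function(block, labels, k_neighbors = 10, m_samples = NULL,
                         seed = 1) {
  lab0 <- block_and_labels(block, labels)
  ord <- order(block$sample_ids)  # canonical sample order
  v <- block$values[, ord, drop = FALSE]
  lab <- lab0[ord]
  n <- ncol(v)
  tab <- table(lab)
  k <- min(k_neighbors, min(tab) - 1L)
  if (k < 1L) stop("each class needs at least k_neighbors + 1 samples",
                   call. = FALSE)
  rng <- apply(v, 1L, function(x) max(x) - min(x))
  scale_ <- ifelse(rng > 0, rng, 1)  # constant features contribute diff 0
  vs <- v / scale_
  m <- m_samples %||% n
  anchors <- if (m >= n) seq_len(n)
             else with_seed(substream_seed(seed, "relieff"),
                            sort(sample.int(n, m)))
  d2 <- as.matrix(stats::dist(t(vs)))^2
  w <- numeric(nrow(v))
  for (a in anchors) {
    same <- which(lab == lab[a]); same <- setdiff(same, a)
    other <- which(lab != lab[a])
    hits <- same[order(d2[a, same], same)][seq_len(k)]
    misses <- other[order(d2[a, other], other)][seq_len(k)]
    dh <- abs(vs[, hits, drop = FALSE] - vs[, a])
    dm <- abs(vs[, misses, drop = FALSE] - vs[, a])
    w <- w + rowSums(dm) / (length(anchors) * k) -
             rowSums(dh) / (length(anchors) * k)
  }
  new_ranking("relieff", block$feature_ids, w)
}

#' Extract the top n features of a ranking
#'
#' For fold-change rankings this delegates to the directional rule of
#' [top_n_fold_change()]; otherwise the first `n` ids of the canonical
#' (weight-descending, id-ascending) order are returned.
#'
#' @param ranking A `feature_ranking`.
#' @param n Number of features (must not exceed the feature count).
#' @return Character vector of feature ids.
#' @export
top_n <- function(ranking, n) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (n > nrow(ranking)) {
    stop(sprintf("n (%d) exceeds the number of ranked features (%d)",
                 n, nrow(ranking)), call. = FALSE)
  }
  if (identical(ranking_method(ranking), "fc")) {
    return(top_n_fold_change(ranking, n))
  }
  ranking$feature_id[seq_len(n)]
}
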