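test_that("fold change matches ratio arithmetic and keeps its sign", {
  # group means 8 vs 2 -> weight ~ 2; reversed -> -2; equal -> 0
  v <- rbind(c(8, 8, 2, 2), c(2, 2, 8, 8), c(5, 5, 5, 5))
  b <- toy_block(v)
  lab <- toy_labels(2, 2)
  r <- rank_fold_change(b, lab)
  w <- r$weight[match(c("f1", "f2", "f3"), r$feature_id)]
  expect_equal(w, c(2, -2, 0), tolerance = 1e-4)
  # ordered by magnitude, ties by id
  expect_equal(r$feature_id[3], "f3")
})

test_that("directional top-n takes n/2 from each direction", {
  v <- rbind(c(8, 8, 1, 1), c(4, 4, 1, 1), c(2, 2, 1, 1),
             c(1, 1, 2, 2), c(1, 1, 4, 4))
  b <- toy_block(v)
  lab <- toy_labels(2, 2)
  r <- rank_fold_change(b, lab)
  expect_setequal(top_n_fold_change(r, 4), c("f1", "f2", "f4", "f5"))
  expect_length(top_n_fold_change(r, 0), 0L)
  # odd n: ceiling(n/2) up, floor(n/2) most strongly down-regulated
  expect_setequal(top_n_fold_change(r, 3), c("f1", "f2", "f5"))
  # all weights one direction: backfill with warning
  bup <- toy_block(rbind(c(8, 8, 1, 1), c(6, 6, 1, 1), c(4, 4, 1, 1),
                         c(2, 2, 1, 1)))
  rup <- rank_fold_change(bup, lab)
  expect_warning(got <- top_n_fold_change(rup, 4), "backfill")
  expect_setequal(got, c("f1", "f2", "f3", "f4"))
})

test_that("OneR weight is the single-rule training accuracy", {
  lab <- toy_labels(4, 4)
  # perfect separator -> 1.0
  b <- toy_block(matrix(c(rep(9, 4), rep(1, 4)), nrow = 1), raw = FALSE)
  expect_equal(rank_oner(b, lab)$weight, 1.0)
  # constant feature, 70% majority -> 0.7
  lab7 <- toy_labels(7, 3)
  b7 <- toy_block(matrix(2, nrow = 1, ncol = 10), raw = FALSE)
  expect_equal(rank_oner(b7, lab7)$weight, 0.7)
})

test_that("OneR weight of an uninformative feature approaches 0.5", {
  set.seed(11)
  n <- 2000
  lab <- sample_labels(paste0("s", 1:n),
                       rep(c("positive", "negative"), each = n / 2))
  v <- matrix(rnorm(n), nrow = 1,
              dimnames = list("f1", paste0("s", 1:n)))
  b <- expression_block(v, block = "mRNA", raw = FALSE)
  w <- rank_oner(b, lab)$weight
  expect_gte(w, 0.5)        # majority rule can never fall below chance
  expect_lt(w, 0.55)        # but carries no real signal
})

test_that("information gain and gain ratio match hand entropy arithmetic", {
  # two bins, (6 pos / 2 neg) and (2 pos / 6 neg)
  lab <- sample_labels(paste0("s", 1:16),
                       rep(c("positive", "negative", "positive", "negative"),
                           c(6, 2, 2, 6)))
  v <- matrix(rep(c(0, 1), each = 8), nrow = 1,
              dimnames = list("f1", paste0("s", 1:16)))
  b <- expression_block(v, block = "mRNA", raw = FALSE)
  ig <- rank_info_gain(b, lab)$weight
  gr <- rank_gain_ratio(b, lab)$weight
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(ig, 1 - h(0.25), tolerance = 1e-12)   # ~0.18872
  expect_equal(gr, ig, tolerance = 1e-12)            # H(V) = 1 here

  # perfect binary predictor, balanced classes -> 1 bit, ratio 1
  lab8 <- toy_labels(4, 4)
  bp <- toy_block(matrix(c(rep(1, 4), rep(0, 4)), nrow = 1), raw = FALSE)
  expect_equal(rank_info_gain(bp, lab8)$weight, 1.0)
  expect_equal(rank_gain_ratio(bp, lab8)$weight, 1.0)

  # constant feature -> both exactly 0 (H(V) = 0 guard)
  bc <- toy_block(matrix(1, nrow = 1, ncol = 8), raw = FALSE)
  expect_identical(rank_info_gain(bc, lab8)$weight, 0)
  expect_identical(rank_gain_ratio(bc, lab8)$weight, 0)
})

test_that("entropy rankers equal a brute-force contingency oracle", {
  # every 2-bin x 2-class table with cells <= 8, against independent
  # entropy arithmetic computed straight from the table
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h_vec <- function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) return(0)
    -sum(plogp(cnt / tot))
  }
  oracle <- function(a, b, c, d) {
    n <- a + b + c + d
    h_y <- h_vec(c(a + c, b + d))
    h_cond <- (a + b) / n * h_vec(c(a, b)) + (c + d) / n * h_vec(c(c, d))
    ig <- max(h_y - h_cond, 0)
    h_v <- h_vec(c(a + b, c + d))
    list(ig = ig, gr = if (h_v <= 0) 0 else ig / h_v)
  }
  grid <- expand.grid(a = 0:8, b = 0:8, c = 0:8, d = 0:8)
  grid <- grid[(grid$a + grid$c) > 0 & (grid$b + grid$d) > 0, ]
  set.seed(20)
  grid <- grid[sample.int(nrow(grid)), ]  # order-independent coverage
  max_dev <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    n <- g$a + g$b + g$c + g$d
    lab <- sample_labels(paste0("s", 1:n),
                         rep(c("positive", "negative",
                               "positive", "negative"),
                             c(g$a, g$b, g$c, g$d)))
    v <- matrix(rep(c(0, 1), c(g$a + g$b, g$c + g$d)), nrow = 1,
                dimnames = list("f1", paste0("s", 1:n)))
    blk <- expression_block(v, block = "mRNA", raw = FALSE)
    ref <- oracle(g$a, g$b, g$c, g$d)
    max_dev <- max(max_dev,
                   abs(rank_info_gain(blk, lab)$weight - ref$ig),
                   abs(rank_gain_ratio(blk, lab)$weight - ref$gr))
  }
  expect_lt(max_dev, 1e-12)
})

test_that("ReliefF scores a constant feature exactly zero and finds signal", {
  lab <- toy_labels(5, 5)
  set.seed(12)
  v <- rbind(rep(2, 10), matrix(rnorm(30), nrow = 3))
  b <- toy_block(v, raw = FALSE)
  r <- rank_relieff(b, lab, k_neighbors = 2)
  expect_identical(r$weight[r$feature_id == "f1"], 0)

  # one signal feature among noise ranks first, across seeds
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 40
    labn <- toy_labels(20, 20)
    vn <- matrix(rnorm(21 * n), nrow = 21)
    vn[1, ] <- ifelse(labn == "positive", 1.5, -1.5) + rnorm(n, sd = 0.4)
    bn <- toy_block(vn, raw = FALSE)
    rn <- rank_relieff(bn, labn, k_neighbors = 5, seed = s)
    expect_identical(rn$feature_id[1], "f1")
  }
})

test_that("ReliefF ranking order survives duplicating every sample", {
  set.seed(9)
  v <- matrix(rnorm(5 * 6), 5, 6)
  v[1, ] <- c(0, 0.2, 0.1, 1, 0.9, 1.1)
  b <- toy_block(v, raw = FALSE)
  lab <- sample_labels(paste0("s", 1:6),
                       rep(c("negative", "positive"), each = 3))
  r1 <- rank_relieff(b, lab, k_neighbors = 1)
  v2 <- cbind(v, v)
  colnames(v2) <- c(paste0("s", 1:6), paste0("t", 1:6))
  rownames(v2) <- paste0("f", 1:5)
  b2 <- expression_block(v2, block = "mRNA", raw = FALSE)
  lab2 <- sample_labels(colnames(v2),
                        rep(rep(c("negative", "positive"), each = 3), 2))
  r2 <- rank_relieff(b2, lab2, k_neighbors = 2)
  expect_identical(r1$feature_id, r2$feature_id)
})

test_that("rankers return permutations with finite weights", {
  set.seed(13)
  b <- toy_block(matrix(rexp(20 * 12), nrow = 20))
  nb <- normalize_block(b)
  lab <- toy_labels(6, 6)
  rankings <- list(rank_fold_change(b, lab), rank_oner(nb, lab),
                   rank_relieff(nb, lab, k_neighbors = 3),
                   rank_info_gain(nb, lab), rank_gain_ratio(nb, lab))
  for (r in rankings) {
    expect_setequal(r$feature_id, b$feature_ids)
    expect_true(all(is.finite(r$weight)))
    expect_true(all(diff(if (attr(r, "method") == "fc") abs(r$weight)
                         else r$weight) <= 1e-12))
  }
})

test_that("label swap negates FC and leaves the other rankers invariant", {
  set.seed(14)
  b <- toy_block(matrix(rexp(10 * 10), nrow = 10))
  nb <- normalize_block(b)
  lab <- toy_labels(5, 5)
  swapped <- sample_labels(names(lab),
                           ifelse(lab == "positive", "negative", "positive"))
  fc1 <- rank_fold_change(b, lab); fc2 <- rank_fold_change(b, swapped)
  expect_equal(fc2$weight[match(fc1$feature_id, fc2$feature_id)],
               -fc1$weight, tolerance = 1e-12)
  for (fn in list(function(l) rank_oner(nb, l),
                  function(l) rank_info_gain(nb, l),
                  function(l) rank_gain_ratio(nb, l),
                  function(l) rank_relieff(nb, l, k_neighbors = 3))) {
    r1 <- fn(lab); r2 <- fn(swapped)
    expect_identical(r1$feature_id, r2$feature_id)
    expect_equal(r1$weight, r2$weight, tolerance = 1e-12)
  }
})

test_that("sample-order permutation never changes a ranking", {
  set.seed(15)
  b <- toy_block(matrix(rexp(12 * 14), nrow = 12))
  lab <- toy_labels(8, 6)
  perm <- sample(b$sample_ids)
  bp <- subset_block(b, samples = perm)
  nb <- normalize_block(b); nbp <- normalize_block(bp)
  pairs <- list(
    list(rank_fold_change(b, lab), rank_fold_change(bp, lab)),
    list(rank_oner(nb, lab), rank_oner(nbp, lab)),
    list(rank_info_gain(nb, lab), rank_info_gain(nbp, lab)),
    list(rank_gain_ratio(nb, lab), rank_gain_ratio(nbp, lab)),
    list(rank_relieff(nb, lab, k_neighbors = 3, m_samples = 8, seed = 4),
         rank_relieff(nbp, lab, k_neighbors = 3, m_samples = 8, seed = 4)))
  for (pr in pairs) {
    expect_identical(pr[[1]]$feature_id, pr[[2]]$feature_id)
    expect_equal(pr[[1]]$weight, pr[[2]]$weight, tolerance = 1e-12)
  }
})

test_that("top_n honours bounds and breaks ties deterministically", {
  lab <- toy_labels(4, 4)
  set.seed(16)
  nb <- normalize_block(toy_block(matrix(rexp(6 * 8), nrow = 6)))
  r <- rank_info_gain(nb, lab)
  expect_length(top_n(r, 6), 6L)
  expect_identical(top_n(r, 1), r$feature_id[1])
  expect_error(top_n(r, 7), "exceeds")
  # exact ties ordered by feature id
  vt <- rbind(c(rep(1, 4), rep(0, 4)), c(rep(1, 4), rep(0, 4)))
  bt <- toy_block(vt, raw = FALSE)
  rt <- rank_info_gain(bt, lab)
  expect_identical(top_n(rt, 1), "f1")
})
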