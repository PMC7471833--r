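#' Expression block container
#'
#' A single feature block: a numeric matrix of expression values with
#' features as rows and samples as columns, tagged with the block it came
#' from (`"mRNA"`, `"miRNA"` or `"combined"`). Values are FPKM-like
#' (nonnegative) before normalization; normalized blocks may hold any real.
#'
#' @param values Numeric matrix, features x samples.
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to the matrix rownames).
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to the matrix colnames).
#' @param block Block tag, one of `"mRNA"`, `"miRNA"`, `"combined"`.
#' @param raw Logical; if `TRUE` (raw expression) values must be finite and
#'   nonnegative.
#' @return An object of class `expression_block`.
#' @export
expression_block <- function(values, feature_ids = rownames(values),
                             sample_ids = colnames(values),
                             block = c("mRNA", "miRNA", "combined"),
                             raw = TRUE) {
  block <- match.arg(block)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)",
         call. = FALSE)
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample identifiers are required", call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (ncol(values) < 1L) stop("empty sample set", call. = FALSE)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature_ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite expression value",
                                    call. = FALSE)
  if (raw && any(values < 0)) {
    stop("negative expression value in raw block", call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, block = block),
            class = "expression_block")
}

#' @export
print.expression_block <- function(x, ...) {
  cat(sprintf("<expression_block> %s: %d features x %d samples\n",
              x$block, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' Subset an expression block by features and/or samples
#'
#' @param block An `expression_block`.
#' @param features Character vector of feature ids to keep (in the given
#'   order), or `NULL` to keep all.
#' @param samples Character vector of sample ids to keep, or `NULL`.
#' @return An `expression_block`.
#' @export
subset_block <- function(block, features = NULL, samples = NULL) {
  stopifnot(inherits(block, "expression_block"))
  features <- features %||% block$feature_ids
  samples <- samples %||% block$sample_ids
  missing_f <- setdiff(features, block$feature_ids)
  missing_s <- setdiff(samples, block$sample_ids)
  if (length(missing_f)) stop("unknown feature ids: ",
                              paste(missing_f, collapse = ", "), call. = FALSE)
  if (length(missing_s)) stop("unknown sample ids: ",
                              paste(missing_s, collapse = ", "), call. = FALSE)
  out <- block
  out$values <- block$values[features, samples, drop = FALSE]
  out$feature_ids <- features
  out$sample_ids <- samples
  attr(out, "normalization") <- attr(block, "normalization")
  out
}

#' Binary sample labels
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param labels Vector of raw label strings, parallel to `sample_ids`.
#' @param positive Raw value mapped to the positive class.
#' @param negative Raw value mapped to the negative class; defaults to every
#'   other observed value.
#' @return A named factor with levels `c("positive", "negative")`.
#' @export
sample_labels <- function(sample_ids, labels, positive = "positive",
                          negative = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in labels",
                                      call. = FALSE)
  if (length(labels) != length(sample_ids)) {
    stop("labels and sample_ids differ in length", call. = FALSE)
  }
  labels <- as.character(labels)
  if (is.null(negative)) {
    cls <- ifelse(labels == positive, "positive", "negative")
  } else {
    bad <- !(labels %in% c(positive, negative))
    if (any(bad)) stop("unmapped label value(s): ",
                       paste(unique(labels[bad]), collapse = ", "),
                       call. = FALSE)
    cls <- ifelse(labels == positive, "positive", "negative")
  }
  out <- factor(cls, levels = c("positive", "negative"))
  names(out) <- sample_ids
  out
}

check_two_classes <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0)) {
    stop("both classes must be present (got only '",
         names(tab)[tab > 0], "')", call. = FALSE)
  }
  invisible(tab)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a UTF-8 tab-delimited file whose first header cell is
#' `feature_id` and whose remaining header cells are sample ids, one row per
#' feature. Identifier uniqueness and numeric parseability are validated
#' with row/column context in error messages.
#'
#' @param path File path.
#' @param block Block tag for the result.
#' @param raw Logical; enforce nonnegativity (raw FPKM-like values).
#' @return An `expression_block`.
#' @export
read_expression <- function(path, block = c("mRNA", "miRNA", "combined"),
                            raw = TRUE) {
  block <- match.arg(block)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty expression file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "feature_id") {
    stop("first header cell must be 'feature_id', got '", header[1L], "'",
         call. = FALSE)
  }
  sample_ids <- header[-1L]
  n_col <- length(header)
  body <- lines[-1L]
  if (!length(body)) stop("expression file has no data rows: ", path,
                          call. = FALSE)
  cells <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop(sprintf("ragged row %d: expected %d columns, found %d",
                 bad + 1L, n_col, widths[bad]), call. = FALSE)
  }
  feature_ids <- vapply(cells, `[[`, character(1L), 1L)
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d ('%s')",
                   i + 1L, j + 1L, cells[[i]][j + 1L]), call. = FALSE)
    }
    values[i, ] <- v
  }
  rownames(values) <- feature_ids
  colnames(values) <- sample_ids
  expression_block(values, block = block, raw = raw)
}

#' Read a tab-delimited sample-label file
#'
#' Two columns, `sample_id` and `label`, with a header row.
#'
#' @param path File path.
#' @inheritParams sample_labels
#' @return A named factor as from [sample_labels()].
#' @export
read_labels <- function(path, positive = "positive", negative = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("label file must have columns 'sample_id' and 'label'",
         call. = FALSE)
  }
  sample_labels(df$sample_id, df$label, positive = positive,
                negative = negative)
}

#' Write an expression block to a tab-delimited file
#'
#' Inverse of [read_expression()]; numbers are written with full precision.
#'
#' @param block An `expression_block`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(block, path) {
  stopifnot(inherits(block, "expression_block"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", block$sample_ids), collapse = "\t"), con)
  body <- apply(block$values, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(block$feature_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Write sample labels to a tab-delimited file
#'
#' @param labels Named factor as from [sample_labels()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), label = as.character(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize one expression block
#'
#' Default normalization is `log2(x + 1)` followed by a per-feature z-score
#' whose center and scale are computed on the training samples only and then
#' applied to every column, so held-out samples never leak into the
#' statistics. Blocks are normalized independently before combination.
#'
#' Zero-variance features on the training data are mapped to all-zero rows
#' rather than dropped, keeping feature indices stable.
#'
#' @param block A raw `expression_block` (not `"combined"`).
#' @param method `"log_zscore"` (default), `"log"` (log2(x+1) only) or
#'   `"none"`.
#' @param train_samples Sample ids used to fit the statistics; default all.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`.
#' @return An `expression_block` with an attached `"normalization"`
#'   attribute recording method, center and scale.
#' @export
normalize_block <- function(block,
                            method = c("log_zscore", "log", "none"),
                            train_samples = NULL,
                            sd_type = c("population", "sample")) {
  stopifnot(inherits(block, "expression_block"))
  method <- match.arg(method)
  sd_type <- match.arg(sd_type)
  if (block$block == "combined") {
    stop("normalize each block separately before combining", call. = FALSE)
  }
  train_samples <- train_samples %||% block$sample_ids
  missing_s <- setdiff(train_samples, block$sample_ids)
  if (length(missing_s)) stop("unknown training sample ids: ",
                              paste(missing_s, collapse = ", "),
                              call. = FALSE)
  v <- block$values
  if (method %in% c("log_zscore", "log")) v <- log2(v + 1)
  center <- scale_ <- NULL
  if (method == "log_zscore") {
    tr <- v[, train_samples, drop = FALSE]
    center <- rowMeans(tr)
    dev <- tr - center
    ss <- rowSums(dev * dev)
    n <- ncol(tr)
    scale_ <- if (sd_type == "population") sqrt(ss / n)
              else sqrt(ss / max(n - 1L, 1L))
    zero_var <- scale_ <= 0
    safe_scale <- ifelse(zero_var, 1, scale_)
    v <- (v - center) / safe_scale
    v[zero_var, ] <- 0  # zero-variance guard: constant rows become zeros
  }
  out <- block
  out$values <- v
  attr(out, "normalization") <- list(method = method, sd_type = sd_type,
                                     train_samples = train_samples,
                                     center = center, scale = scale_)
  out
}

#' Student's t-test feature filter
#'
#' Per-feature two-sample t-test between the positive and negative groups,
#' computed on the stated samples (typically the training set only).
#' Features with `p < alpha` are retained. The classical equal-variance
#' Student form is the default; Welch's unequal-variance form is available
#' by flag. Features constant in both groups get `p = 1`.
#'
#' @param block An `expression_block`.
#' @param labels Named factor from [sample_labels()].
#' @param alpha Significance cut-off (default 0.05).
#' @param samples Sample ids to test on; default all samples of the block.
#' @param welch Logical; use the unequal-variance form.
#' @return An object of class `filter_result` with fields `retained`,
#'   `p_values` (named), and `alpha`.
#' @export
ttest_filter <- function(block, labels, alpha = 0.05, samples = NULL,
                         welch = FALSE) {
  stopifnot(inherits(block, "expression_block"))
  samples <- samples %||% block$sample_ids
  lab <- labels[samples]
  if (anyNA(lab)) stop("labels missing for some samples", call. = FALSE)
  check_two_classes(lab)
  if (any(table(lab) < 2L)) {
    stop("each class needs at least 2 samples for the t-test", call. = FALSE)
  }
  v <- block$values[, samples, drop = FALSE]
  pos <- v[, lab == "positive", drop = FALSE]
  neg <- v[, lab == "negative", drop = FALSE]
  n1 <- ncol(pos); n2 <- ncol(neg)
  m1 <- rowMeans(pos); m2 <- rowMeans(neg)
  ss1 <- rowSums((pos - m1)^2)
  ss2 <- rowSums((neg - m2)^2)
  if (welch) {
    v1 <- ss1 / (n1 - 1L); v2 <- ss2 / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  } else {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2L, length(m1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 1  # both-groups-constant features
  names(p) <- block$feature_ids
  structure(list(retained = block$feature_ids[p < alpha], p_values = p,
                 statistic = tstat, alpha = alpha, welch = welch),
            class = "filter_result")
}

#' Train/test split of the sample set
#'
#' Uniform random split by default, mirroring simple random selection of the
#' training set; a stratified option preserves class proportions in both
#' parts. The training size is `floor(n * train_fraction)` (per stratum when
#' stratified).
#'
#' @param labels Named factor from [sample_labels()].
#' @param train_fraction Fraction of samples assigned to training
#'   (default 0.8).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified Logical; preserve class proportions.
#' @return A list with `train`, `test` (character sample ids) and `seed`,
#'   of class `split_assignment`.
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed,
                             stratified = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_config("train_fraction", "must be strictly between 0 and 1")
  }
  ids <- names(labels)
  train <- with_seed(substream_seed(seed, "split"), {
    if (stratified) {
      unlist(lapply(split(ids, labels[ids]), function(g)
        sample(g, floor(length(g) * train_fraction))), use.names = FALSE)
    } else {
      sample(ids, floor(length(ids) * train_fraction))
    }
  })
  train <- ids[ids %in% train]  # canonical order
  test <- setdiff(ids, train)
  if (!stratified &&
      (length(unique(labels[train])) < 2L ||
       length(unique(labels[test])) < 2L)) {
    warning("a split part contains a single class; consider stratified = TRUE",
            call. = FALSE)
  }
  structure(list(train = train, test = test, seed = seed,
                 stratified = stratified), class = "split_assignment")
}

#' Combine separately normalized blocks into one multiscale block
#'
#' Row-concatenates the blocks over their shared sample set. Feature ids are
#' prefixed with their block tag (`"mRNA:"`, `"miRNA:"`) so the provenance
#' of every feature is recoverable from the combined matrix.
#'
#' @param blocks A list of `expression_block` objects sharing one sample
#'   set, each already normalized.
#' @return An `expression_block` with tag `"combined"`.
#' @export
combine_blocks <- function(blocks) {
  stopifnot(is.list(blocks), all(vapply(blocks, inherits, logical(1L),
                                        "expression_block")))
  blocks <- Filter(function(b) length(b$feature_ids) > 0L, blocks)
  if (!length(blocks)) stop("no non-empty blocks to combine", call. = FALSE)
  ref <- blocks[[1L]]$sample_ids
  for (b in blocks[-1L]) {
    if (!setequal(b$sample_ids, ref)) {
      diffs <- c(setdiff(ref, b$sample_ids), setdiff(b$sample_ids, ref))
      stop("sample-set mismatch between blocks: ",
           paste(diffs, collapse = ", "), call. = FALSE)
    }
  }
  mats <- lapply(blocks, function(b) {
    m <- b$values[, ref, drop = FALSE]
    rownames(m) <- prefix_features(b$feature_ids, b$block)
    m
  })
  combined <- do.call(rbind, mats)
  expression_block(combined, block = "combined", raw = FALSE)
}

prefix_features <- function(ids, block) {
  if (block == "combined") ids else paste0(block, ":", ids)
}

#' Split combined feature ids back into block and bare id
#'
#' @param ids Character vector of (possibly prefixed) feature ids.
#' @return A data frame with columns `feature_id`, `block`, `bare_id`.
#' @export
feature_provenance <- function(ids) {
  has <- grepl("^(mRNA|miRNA):", ids)
  block <- ifelse(has, sub(":.*$", "", ids), NA_character_)
  bare <- ifelse(has, sub("^(mRNA|miRNA):", "", ids), ids)
  data.frame(feature_id = ids, block = block, bare_id = bare,
             stringsAsFactors = FALSE)
}

#' Read a flat YAML-style key/value configuration file
#'
#' Supports `key: value` lines, `#` comments and blank lines; values are
#' auto-typed to numeric or logical where unambiguous. Nested structures
#' are deliberately out of scope.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("unparseable config line: '", ln, "'",
                              call. = FALSE)
    key <- m[2L]; val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (val %in% c("true", "TRUE", "yes")) TRUE
                  else if (val %in% c("false", "FALSE", "no")) FALSE
                  else val
  }
  out
}
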