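#' Configuration for the synthetic multiscale expression generator
#'
#' The generator emulates the shape of paired tumor expression profiles: a
#' wide mRNA-scale block (thousands of features), a narrow microRNA-scale
#' block (hundreds), a binary phenotype, and a planted subset of
#' class-associated features in each block. Values are FPKM-like:
#' log2-scale Gaussian, exponentiated, hence nonnegative and right-skewed.
#'
#' @param n_samples Number of samples.
#' @param class_balance Fraction of positive samples, in (0, 1). Default
#'   0.75, a typical receptor-positive majority; configurable because real
#'   cohort proportions vary.
#' @param n_mrna,n_mirna Number of mRNA-scale / miRNA-scale features.
#' @param n_informative_mrna,n_informative_mirna Planted class-associated
#'   features per block.
#' @param effect_size Standardized mean shift of planted features between
#'   classes, in units of the within-class SD on log2 scale.
#' @param noise_sd Within-class SD on log2 scale (default 1).
#' @param seed Integer seed; drives named sub-streams per stage.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 200, class_balance = 0.75,
                         n_mrna = 2000, n_mirna = 300,
                         n_informative_mrna = 50, n_informative_mirna = 10,
                         effect_size = 2, noise_sd = 1, seed = 1) {
  chk_count <- function(x, field, min = 1) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
      stop_config(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_count(n_samples, "n_samples", min = 4)
  chk_count(n_mrna, "n_mrna")
  chk_count(n_mirna, "n_mirna")
  chk_count(n_informative_mrna, "n_informative_mrna", min = 0)
  chk_count(n_informative_mirna, "n_informative_mirna", min = 0)
  if (!(length(class_balance) == 1L && class_balance > 0 &&
        class_balance < 1)) {
    stop_config("class_balance", "must be in (0, 1)")
  }
  if (n_informative_mrna > n_mrna) {
    stop_config("n_informative_mrna", "cannot exceed n_mrna")
  }
  if (n_informative_mirna > n_mirna) {
    stop_config("n_informative_mirna", "cannot exceed n_mirna")
  }
  if (!(length(effect_size) == 1L && is.finite(effect_size) &&
        effect_size >= 0)) {
    stop_config("effect_size", "must be a single nonnegative number")
  }
  if (!(length(noise_sd) == 1L && is.finite(noise_sd) && noise_sd > 0)) {
    stop_config("noise_sd", "must be a single positive number")
  }
  chk_count(seed, "seed", min = 0)
  structure(list(n_samples = as.integer(n_samples),
                 class_balance = class_balance,
                 n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
                 n_informative_mrna = as.integer(n_informative_mrna),
                 n_informative_mirna = as.integer(n_informative_mirna),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

gen_block <- function(config, n_feat, n_inf, block, labels, seed) {
  n <- config$n_samples
  with_seed(seed, {
    # per-feature baseline abundance on log2 scale
    mu <- stats::rnorm(n_feat, mean = 5, sd = 2)
    z <- matrix(stats::rnorm(n_feat * n, sd = config$noise_sd),
                nrow = n_feat) + mu
    direction <- integer(0)
    if (n_inf > 0) {
      # planted features are the first n_inf rows; direction alternates
      # deterministically by index so directional top-n/2 selection is
      # exercisable
      direction <- ifelse(seq_len(n_inf) %% 2L == 1L, 1L, -1L)
      delta <- config$effect_size * config$noise_sd
      shift <- outer(direction * delta / 2,
                     ifelse(labels == "positive", 1, -1))
      z[seq_len(n_inf), ] <- z[seq_len(n_inf), , drop = FALSE] + shift
    }
    values <- 2^z  # exponentiate: nonnegative, right-skewed, FPKM-like
    ids <- sprintf("%s_%05d", tolower(block), seq_len(n_feat))
    rownames(values) <- ids
    colnames(values) <- names(labels)
    list(block = expression_block(values, block = block),
         truth = data.frame(
           feature_id = ids, block = block,
           informative = as.integer(seq_len(n_feat) <= n_inf),
           direction = c(direction, rep.int(0L, n_feat - n_inf)),
           stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic multiscale expression dataset
#'
#' Produces an mRNA-scale block, a miRNA-scale block, binary sample labels
#' and a ground-truth table naming the planted features and their direction
#' (+1 up-regulated, -1 down-regulated in the positive class). Planted
#' features have a class-mean separation of `effect_size * noise_sd` on
#' log2 scale; non-informative features have identical class distributions.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list with elements `mrna`, `mirna` (each an
#'   `expression_block`), `labels` (named factor) and `truth` (data frame
#'   with columns `feature_id`, `block`, `informative`, `direction`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  n_pos <- round(n * config$class_balance)
  n_pos <- min(max(n_pos, 2L), n - 2L)  # both classes usable downstream
  sample_ids <- sprintf("S%04d", seq_len(n))
  labels <- with_seed(substream_seed(config$seed, "labels"), {
    cls <- sample(rep(c("positive", "negative"), c(n_pos, n - n_pos)))
    sample_labels(sample_ids, cls)
  })
  mr <- gen_block(config, config$n_mrna, config$n_informative_mrna, "mRNA",
                  labels, substream_seed(config$seed, "mrna"))
  mi <- gen_block(config, config$n_mirna, config$n_informative_mirna,
                  "miRNA", labels, substream_seed(config$seed, "mirna"))
  list(mrna = mr$block, mirna = mi$block, labels = labels,
       truth = rbind(mr$truth, mi$truth), config = config)
}

#' Write a generated dataset as tab-delimited fixtures
#'
#' Emits `mrna.tsv`, `mirna.tsv`, `labels.tsv` and a `truth.tsv` sidecar
#' (columns `feature_id`, `block`, `informative`, `direction`) that
#' round-trip losslessly through [read_expression()] / [read_labels()].
#'
#' @param dataset A list as returned by [generate_dataset()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(mrna = file.path(directory, "mrna.tsv"),
             mirna = file.path(directory, "mirna.tsv"),
             labels = file.path(directory, "labels.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_expression(dataset$mrna, paths[["mrna"]])
  write_expression(dataset$mirna, paths[["mirna"]])
  write_labels(dataset$labels, paths[["labels"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Directory containing `mrna.tsv`, `mirna.tsv`,
#'   `labels.tsv` and `truth.tsv`.
#' @return A list with the same shape as [generate_dataset()] output
#'   (minus `config`).
#' @export
read_fixture <- function(directory) {
  list(mrna = read_expression(file.path(directory, "mrna.tsv"), "mRNA"),
       mirna = read_expression(file.path(directory, "mirna.tsv"), "miRNA"),
       labels = read_labels(file.path(directory, "labels.tsv")),
       truth = utils::read.table(file.path(directory, "truth.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE))
}
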