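# Synthetic expression data with known ground truth.
#
# The generator emulates the structure the prediction pipeline faces on real
# repository data: a genes x samples value grid; a binary sample attribute
# with class imbalance; a small set of informative genes whose log2 mean is
# shifted in the minority class; per-sample library-scale factors (so raw
# values are not comparable across samples and normalization is
# non-trivial); and missing-completely-at-random gaps in the metadata.

#' Configuration for the synthetic-data generator
#'
#' Values are log-normal: `2^(b_g + effect + noise) * scale_s`, with per-gene
#' baselines `b_g ~ U(3, 10)` on the log2 scale.  Informative genes gain a
#' log2 mean shift of `effect_size` in the minority ("pos") class.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_informative number of genes carrying the class signal.
#' @param effect_size log2-scale mean shift of informative genes in the
#'   minority class.
#' @param minority_fraction probability a sample is in the minority class,
#'   in (0, 0.5].
#' @param noise_sd within-class log2-scale standard deviation.
#' @param library_scale_range lower/upper bound of the per-sample
#'   multiplicative library-size factor.
#' @param missing_rate probability a metadata cell is masked as missing.
#' @param seed integer seed; the same configuration always yields the same
#'   dataset.
#' @return object of class `synth_config`.
#' @export
synthetic_config <- function(n_samples = 600, n_genes = 2000,
                             n_informative = 50, effect_size = 1.0,
                             minority_fraction = 0.25, noise_sd = 1.0,
                             library_scale_range = c(0.5, 2),
                             missing_rate = 0.2, seed = 1) {
  check_num <- function(x, name, lo = -Inf, hi = Inf, len = 1,
                        integer = FALSE) {
    if (!is.numeric(x) || length(x) != len || anyNA(x) ||
        any(x < lo) || any(x > hi) || (integer && any(x != round(x)))) {
      stop("invalid configuration field: ", name)
    }
  }
  check_num(n_samples, "n_samples", lo = 4, integer = TRUE)
  check_num(n_genes, "n_genes", lo = 1, integer = TRUE)
  check_num(n_informative, "n_informative", lo = 0, hi = n_genes,
            integer = TRUE)
  check_num(effect_size, "effect_size", lo = 0)
  check_num(minority_fraction, "minority_fraction", lo = 1e-9, hi = 0.5)
  check_num(noise_sd, "noise_sd", lo = 0)
  check_num(library_scale_range, "library_scale_range", lo = 1e-12, len = 2)
  if (library_scale_range[1] > library_scale_range[2]) {
    stop("invalid configuration field: library_scale_range")
  }
  check_num(missing_rate, "missing_rate", lo = 0, hi = 1 - 1e-9)
  check_num(seed, "seed", integer = TRUE)
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      n_informative = as.integer(n_informative), effect_size = effect_size,
      minority_fraction = minority_fraction, noise_sd = noise_sd,
      library_scale_range = library_scale_range, missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic expression dataset with known truth
#'
#' @param config a [synthetic_config()].
#' @return list with `expression` (genes x samples matrix), `metadata`
#'   (data.frame: `sample_id`, `group` with `NA` for masked cells) and
#'   `truth` (list: `labels` named +1/-1 vector for all samples including
#'   masked ones, `informative_genes`, `config`).
#' @export
synth_generate <- function(config) {
  if (!inherits(config, "synth_config")) {
    config <- do.call(synthetic_config, config)
  }
  n <- config$n_samples
  g <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(g))
  sample_ids <- sprintf("S%05d", seq_len(n))
  withr_seed(config$seed, {
    baseline <- stats::runif(g, 3, 10)
    labels <- ifelse(stats::runif(n) < config$minority_fraction, 1, -1)
    informative <- gene_ids[seq_len(config$n_informative)]
    shift <- matrix(0, g, n)
    if (config$n_informative > 0) {
      shift[seq_len(config$n_informative), labels == 1] <- config$effect_size
    }
    logv <- baseline + shift +
      matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n)
    scale_s <- stats::runif(n, config$library_scale_range[1],
                            config$library_scale_range[2])
    M <- sweep(2^logv, 2, scale_s, "*")
    dimnames(M) <- list(gene_ids, sample_ids)
    group <- ifelse(labels == 1, "pos", "neg")
    masked <- stats::runif(n) < config$missing_rate
    group[masked] <- NA_character_
  })
  names(labels) <- sample_ids
  list(
    expression = M,
    metadata = data.frame(sample_id = sample_ids, group = group,
                          stringsAsFactors = FALSE),
    truth = list(labels = labels, informative_genes = informative,
                 config = config)
  )
}

#' Oracle predicted probabilities from known labels
#'
#' A test double for downstream experiments: each sample's probability of
#' the +1 class is `1 - error_rate` for true positives and `error_rate` for
#' true negatives, and is flipped across 0.5 with probability `error_rate`.
#' With `error_rate = 0` the probabilities are exactly 1 and 0.
#'
#' @param truth the `truth` element of [synth_generate()] output, or any
#'   list with a named `labels` +1/-1 vector.
#' @param error_rate misclassification probability, in \[0, 0.5).
#' @param seed integer seed.
#' @return named numeric vector of probabilities in \[0, 1\].
#' @export
oracle_probabilities <- function(truth, error_rate, seed = 1) {
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  labels <- truth$labels
  p <- ifelse(labels == 1, 1 - error_rate, error_rate)
  withr_seed(seed, {
    flip <- stats::runif(length(p)) < error_rate
  })
  p[flip] <- 1 - p[flip]
  names(p) <- names(labels)
  p
}
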