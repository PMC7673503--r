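# Small data builders shared by the tests.

# Random expression-like matrix with dimnames.
rand_matrix <- function(n_genes, n_samples, seed = 1, lambda = 50) {
  set.seed(seed)
  M <- matrix(rpois(n_genes * n_samples, lambda) + 1, n_genes, n_samples)
  dimnames(M) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  M
}

# Samples x features toy with a separable 2-gene signal.
separable_toy <- function(n = 60, sd = 0.1, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(rnorm(n * 2, sd = sd), n, 2,
              dimnames = list(sprintf("s%02d", seq_len(n)), c("gA", "gB")))
  X[y == 1, ] <- X[y == 1, ] + 5
  list(X = X, y = setNames(y, rownames(X)))
}

# Small labeled synthetic dataset for pipeline-level tests.
small_synth <- function(n = 120, genes = 200, informative = 20, effect = 1.5,
                        minority = 0.3, noise = 0.7, missing = 0, seed = 1) {
  d <- synth_generate(synthetic_config(
    n_samples = n, n_genes = genes, n_informative = informative,
    effect_size = effect, minority_fraction = minority, noise_sd = noise,
    missing_rate = missing, seed = seed
  ))
  d$labels <- d$truth$labels
  d
}

fast_spec <- function(...) {
  args <- list(algorithm = "lasso", normalization = "rank",
               gene_mode = "fixed-10", rfe_step = 0.3, tuning_budget = 3)
  do.call(model_spec, utils::modifyList(args, list(...)))
}
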