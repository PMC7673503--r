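# Pre-classification stages: Welch t-test gene screening, recursive feature
# elimination, and SMOTE oversampling of the minority class.

# Vectorized Welch two-sample t-test over matrix rows.  Returns t, df and
# two-sided p for every row; degenerate rows (zero variance in both groups)
# get t = 0, p = 1 when the means agree and p = 0 otherwise.
row_welch <- function(X, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  X1 <- X[, idx1, drop = FALSE]; X2 <- X[, idx2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    same <- degenerate & (m1 == m2)
    t[same] <- 0; p[same] <- 1; df[same] <- n1 + n2 - 2
    diff <- degenerate & (m1 != m2)
    t[diff] <- sign(m1 - m2)[diff] * Inf; p[diff] <- 0
    df[diff] <- n1 + n2 - 2
  }
  data.frame(gene_id = rownames(X), t = t, df = df, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen genes by Welch two-sample t-test
#'
#' Tests every gene for a mean difference between the two label classes and
#' flags genes with two-sided p below `alpha` as candidate predictors.
#'
#' @param X numeric matrix, genes x samples, restricted to labeled samples.
#' @param labels named +1/-1 vector over the columns of `X` (or a
#'   `pcap_labels` object).
#' @param alpha significance level for the pass flag.
#' @return data.frame with columns `gene_id`, `t`, `df`, `p`, `pass`.
#' @export
welch_screen <- function(X, labels, alpha = 0.1) {
  if (inherits(labels, "pcap_labels")) labels <- labels$labels
  if (is.null(names(labels))) stop("labels must be named by sample id")
  missing_s <- setdiff(names(labels), colnames(X))
  if (length(missing_s)) {
    stop("labeled sample(s) absent from matrix: ",
         paste(utils::head(missing_s, 5), collapse = ", "))
  }
  idx1 <- match(names(labels)[labels == 1], colnames(X))
  idx2 <- match(names(labels)[labels == -1], colnames(X))
  res <- row_welch(X, idx1, idx2)
  res$pass <- res$p < alpha
  res
}

#' SMOTE oversampling of the minority class
#'
#' Equalizes class counts by adding synthetic minority samples.  Each
#' synthetic sample is `x_i + u * (x_nn - x_i)` with `u ~ U(0, 1)`, where
#' `x_nn` is one of the `k_neighbors` nearest minority neighbours of
#' minority sample `x_i`, chosen uniformly.  Original samples are never
#' modified; synthetic rows are named `synth1`, `synth2`, ...
#'
#' @param X numeric matrix, samples x features.
#' @param y +1/-1 vector aligned with the rows of `X`.
#' @param k_neighbors number of nearest neighbours to interpolate towards;
#'   capped at minority size - 1.
#' @param seed integer seed.
#' @return list with elements `X` (augmented matrix) and `y`.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1) {
  if (nrow(X) != length(y)) stop("X rows and y must align")
  counts <- table(factor(y, levels = c(-1, 1)))
  minority <- if (counts["1"] <= counts["-1"]) 1 else -1
  n_min <- sum(y == minority)
  n_need <- abs(counts[["1"]] - counts[["-1"]])
  if (n_need == 0) return(list(X = X, y = y))
  if (n_min < 2) stop("minority class has fewer than 2 samples; SMOTE needs a neighbour")
  k <- min(k_neighbors, n_min - 1)
  Xm <- X[y == minority, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  # k nearest minority neighbours of each minority sample
  nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- matrix(nn, nrow = k)
  synth <- matrix(0, n_need, ncol(X))
  withr_seed(seed, {
    base_idx <- rep_len(sample.int(n_min), n_need)
    pick <- sample.int(k, n_need, replace = TRUE)
    u <- stats::runif(n_need)
  })
  for (s in seq_len(n_need)) {
    i <- base_idx[s]
    j <- nn[pick[s], i]
    synth[s, ] <- Xm[i, ] + u[s] * (Xm[j, ] - Xm[i, ])
  }
  colnames(synth) <- colnames(X)
  rownames(synth) <- sprintf("synth%d", seq_len(n_need))
  list(
    X = rbind(X, synth),
    y = c(y, rep(minority, n_need))
  )
}

#' Recursive feature elimination
#'
#' Starting from the screened genes, repeatedly fits the base model, ranks
#' genes by model-native importance (absolute coefficients for linear
#' models, impurity/gain importance for tree ensembles) and drops the
#' least-important `step` fraction.  In `"auto"` mode a 3-fold
#' cross-validated AUROC is recorded at every set size and the
#' best-scoring set of at most 100 genes is returned (ties favour the
#' smaller set); in `"fixed-10"`/`"fixed-25"` mode elimination simply
#' proceeds to exactly k genes.
#'
#' @param X numeric matrix, samples x genes (screened genes only).
#' @param y +1/-1 vector aligned with rows of `X`.
#' @param spec a [model_spec()]; its algorithm drives fitting and
#'   importance.
#' @param mode `"auto"`, `"fixed-10"` or `"fixed-25"`.
#' @param inner_folds folds for the auto-mode CV score.
#' @param seed integer seed.
#' @param step fraction of remaining genes dropped per iteration.
#' @param max_auto largest set size returned in auto mode.
#' @return character vector of selected gene ids, ordered by decreasing
#'   importance in the final fit.
#' @export
rfe_select <- function(X, y, spec, mode = c("auto", "fixed-10", "fixed-25"),
                       inner_folds = 3, seed = 1, step = 0.1,
                       max_auto = 100) {
  mode <- match.arg(mode)
  # auto mode stops at 2 genes: a 1-gene model cannot be scored by every
  # backend and a singleton signature is never the CV optimum in practice
  target <- switch(mode, auto = 2L, `fixed-10` = 10L, `fixed-25` = 25L)
  genes <- colnames(X)
  if (is.null(genes)) stop("X must have gene ids as colnames")
  if (length(genes) == 1) return(genes)
  if (mode != "auto" && length(genes) <= target) {
    warning(sprintf(
      "only %d genes passed screening; returning all (requested %d)",
      length(genes), target
    ))
    return(rank_by_importance(X, y, spec, seed))
  }
  history <- list()
  it <- 0
  repeat {
    it <- it + 1
    if (mode == "auto" && length(genes) <= max_auto) {
      score <- cv_auroc(X[, genes, drop = FALSE], y, spec, inner_folds,
                        derive_seed(seed, 7, it))
      history[[length(history) + 1]] <- list(genes = genes, score = score)
    }
    if (length(genes) <= target) break
    ranked <- rank_by_importance(X[, genes, drop = FALSE], y, spec,
                                 derive_seed(seed, 11, it))
    n_drop <- max(1L, floor(step * length(genes)))
    n_drop <- min(n_drop, length(genes) - target)
    genes <- ranked[seq_len(length(genes) - n_drop)]
  }
  if (mode == "auto") {
    scores <- vapply(history, `[[`, numeric(1), "score")
    sizes <- vapply(history, function(h) length(h$genes), integer(1))
    best <- order(-scores, sizes)[1]
    history[[best]]$genes
  } else {
    genes
  }
}

# Genes of X ordered by decreasing model-native importance.
rank_by_importance <- function(X, y, spec, seed) {
  fit <- fit_classifier(X, y, spec$algorithm,
                        default_params(spec$algorithm, ncol(X)),
                        seed = seed, importance = TRUE)
  imp <- classifier_importance(fit)
  imp <- imp[colnames(X)]
  imp[is.na(imp)] <- 0
  names(sort(imp, decreasing = TRUE))
}

# Mean held-out AUROC of the base model over a small stratified CV.
cv_auroc <- function(X, y, spec, folds, seed) {
  fold <- stratified_folds(y, folds, seed)
  scores <- c()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) next
    fit <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec$algorithm,
                          default_params(spec$algorithm, ncol(X)),
                          seed = derive_seed(seed, f))
    p <- classifier_predict(fit, X[!tr, , drop = FALSE])
    scores <- c(scores, auroc(y[!tr], p))
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}
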