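# Independent brute-force re-implementations used as oracles.  These are
# deliberately naive (explicit sorts, loops and counts) and share no code
# with the package internals they check, except where a fitted model itself
# is the shared primitive (nested-CV oracle).

# Quantile normalization by literal sort-average-unsort.
oracle_quantile <- function(M) {
  sorted <- apply(M, 2, sort)
  ref <- rowMeans(sorted)
  out <- M
  for (j in seq_len(ncol(M))) {
    ord <- order(M[, j])
    vals <- numeric(nrow(M))
    vals[ord] <- ref
    # ties: average the assigned reference values across tied positions
    for (v in unique(M[, j])) {
      idx <- which(M[, j] == v)
      if (length(idx) > 1) vals[idx] <- mean(vals[idx])
    }
    out[, j] <- vals
  }
  out
}

# Precision/recall at a percentile cutoff by explicit sorting and counting.
oracle_pr <- function(probs, labels, p) {
  t <- as.numeric(quantile(probs, p / 100, type = 7))
  pred_pos <- which(probs >= t)
  tp <- 0
  for (i in pred_pos) if (labels[i] == 1) tp <- tp + 1
  n_pos <- sum(labels == 1)
  list(
    precision = if (length(pred_pos) == 0) NA_real_ else tp / length(pred_pos),
    recall = if (n_pos == 0) 0 else tp / n_pos
  )
}

# Exhaustive argmax-with-min-tie-break cutoff selection.
oracle_select_cutoff <- function(prec, rec, x, n_pos = NULL, grid = 50:99) {
  k <- nrow(prec)
  counts <- integer(length(grid))
  for (gi in seq_along(grid)) {
    for (f in seq_len(k)) {
      if (!is.na(prec[f, gi]) && prec[f, gi] >= x / 100) {
        counts[gi] <- counts[gi] + 1
      }
    }
  }
  if (max(counts) == 0) {
    return(list(percentile = max(grid), recall = 0, attainable = FALSE))
  }
  best <- max(counts)
  sel_idx <- min(which(counts == best))
  keep <- seq_len(k)
  if (!is.null(n_pos)) keep <- keep[n_pos > 0]
  rec_val <- if (length(keep) == 0) 0 else mean(rec[keep, sel_idx])
  list(percentile = grid[sel_idx], recall = rec_val, attainable = TRUE)
}

# Stratified fold assignment replicated from its documented behaviour:
# per class (in table order), a seeded permutation dealt round-robin.
oracle_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in names(table(y))) {
    idx <- which(y == as.numeric(cls))
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Nested-CV PCAP estimation with every fold split materialized explicitly.
# Model fitting/prediction reuses the package pipeline (the shared
# primitive); all splitting, sweeping, selection and aggregation logic is
# re-derived here by brute force.
oracle_estimate_pcap <- function(X, y, spec, x, outer_folds, inner_folds,
                                 seed) {
  ds <- pcapmeta:::derive_seed
  grid <- 50:99
  ofold <- oracle_folds(y, outer_folds, ds(seed, 101))
  P <- R <- AP <- numeric(outer_folds)
  att <- logical(outer_folds)
  for (i in seq_len(outer_folds)) {
    tr <- names(y)[ofold != i]
    te <- names(y)[ofold == i]
    ifold <- oracle_folds(y[tr], inner_folds, ds(seed, 102, i))
    prec <- rec <- matrix(NA_real_, inner_folds, length(grid))
    npos <- integer(inner_folds)
    for (j in seq_len(inner_folds)) {
      itr <- tr[ifold != j]
      ival <- tr[ifold == j]
      pl <- fit_pipeline(X[, itr, drop = FALSE], y[itr], spec,
                         seed = ds(seed, 103, i, j))
      pv <- predict(pl, X[, ival, drop = FALSE])
      for (gi in seq_along(grid)) {
        r <- oracle_pr(pv, y[ival], grid[gi])
        prec[j, gi] <- r$precision
        rec[j, gi] <- r$recall
      }
      npos[j] <- sum(y[ival] == 1)
    }
    sel <- oracle_select_cutoff(prec, rec, x, n_pos = npos, grid = grid)
    P[i] <- sel$percentile
    R[i] <- if (sel$attainable) sel$recall else 0
    att[i] <- sel$attainable
    pl_o <- fit_pipeline(X[, tr, drop = FALSE], y[tr], spec,
                         seed = ds(seed, 104, i))
    pt <- predict(pl_o, X[, te, drop = FALSE])
    AP[i] <- oracle_pr(pt, y[te], sel$percentile)$precision
  }
  list(pcap = mean(R), percentile = P, inner_recall = R,
       achieved_precision = AP, attainable = att,
       cutoff = min(99, max(50, round(mean(P)))))
}

# Confusion-matrix F1 by explicit counting.
oracle_f1 <- function(labels, predicted) {
  tp <- fp <- fn <- 0
  for (i in seq_along(labels)) {
    if (predicted[i] == 1 && labels[i] == 1) tp <- tp + 1
    if (predicted[i] == 1 && labels[i] == -1) fp <- fp + 1
    if (predicted[i] == -1 && labels[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp == 0) NA else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA else tp / (tp + fn)
  if (is.na(prec) || is.na(recall) || prec + recall == 0) return(0)
  2 * prec * recall / (prec + recall)
}
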