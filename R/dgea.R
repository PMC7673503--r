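# Differential gene expression with true vs predicted group labels.
#
# The question these tools answer: if a grouping variable was predicted
# rather than observed, how much of the differential-expression signal that
# the true labels would give is recovered?  Two experiment designs are
# provided: a five-arm fold-rotation comparison (true labels, predicted
# labels at two precision targets, a freshly "collected" fold, permuted
# labels) and a sweep over the two-sided confidence cutoff c.

#' Per-gene two-sample t-test (differential expression)
#'
#' Welch t-test per gene between two disjoint sample groups, after log2
#' transformation of the values (with a pseudocount).  Genes with adjusted
#' p below `threshold` form the significant set.
#'
#' @param X numeric matrix, genes x samples (raw values).
#' @param group1,group2 disjoint character vectors of sample ids, each of
#'   size at least 2.
#' @param threshold significance threshold on the (adjusted) p-value.
#' @param log2_transform log2-transform values before testing.
#' @param pseudocount added before the log2 transform.
#' @param adjust multiple-testing correction passed to [stats::p.adjust()];
#'   `"none"` (default) mirrors plain overlap-count designs, `"BH"` gives
#'   Benjamini-Hochberg.
#' @return object of class `deg_list` with per-gene statistics and the
#'   significant gene set.
#' @export
deg_ttest <- function(X, group1, group2, threshold = 0.05,
                      log2_transform = TRUE, pseudocount = 1,
                      adjust = "none") {
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 samples")
  }
  missing_s <- setdiff(c(group1, group2), colnames(X))
  if (length(missing_s)) {
    stop("sample(s) absent from matrix: ",
         paste(utils::head(missing_s, 5), collapse = ", "))
  }
  Xs <- X[, c(group1, group2), drop = FALSE]
  if (log2_transform) Xs <- log2(Xs + pseudocount)
  res <- row_welch(Xs, seq_along(group1),
                   length(group1) + seq_along(group2))
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  sig <- res$gene_id[res$p_adj < threshold]
  structure(
    list(stats = res, threshold = threshold, adjust = adjust,
         significant = sig, genes = rownames(X),
         n1 = length(group1), n2 = length(group2)),
    class = "deg_list"
  )
}

#' Overlap between two differential-expression gene lists
#'
#' @param a reference `deg_list` (the overlap percentage is relative to its
#'   significant set).
#' @param b comparison `deg_list`; must share the gene universe of `a`.
#' @return list with `n_a`, `n_b`, `n_overlap` and `percent`
#'   (`100 * n_overlap / n_a`; NA when `a` has no significant genes).
#' @export
deg_overlap <- function(a, b) {
  if (!setequal(a$genes, b$genes)) {
    stop("gene universes differ between the two lists")
  }
  n_int <- length(intersect(a$significant, b$significant))
  list(
    n_a = length(a$significant), n_b = length(b$significant),
    n_overlap = n_int,
    percent = if (length(a$significant) == 0) NA_real_
              else 100 * n_int / length(a$significant)
  )
}

#' Out-of-fold predicted probabilities from a k-fold cross-validation
#'
#' Fits the pipeline on each training split and predicts the held-out fold,
#' yielding one probability per sample from a model that never saw it.
#'
#' @param X,y data as for [fit_pipeline()].
#' @param spec a [model_spec()].
#' @param folds number of stratified folds.
#' @param seed integer seed.
#' @return list with `probs` (named vector) and `fold` (named fold ids).
#' @export
cv_probabilities <- function(X, y, spec, folds = 10, seed = spec$seed) {
  fold <- stratified_folds(y, folds, derive_seed(seed, 301))
  probs <- rep(NA_real_, length(y))
  names(probs) <- names(y)
  for (f in seq_len(folds)) {
    tr <- names(y)[fold != f]
    te <- names(y)[fold == f]
    pl <- fit_pipeline(X[, tr, drop = FALSE], y[tr], spec,
                       seed = derive_seed(seed, 302, f))
    probs[te] <- predict(pl, X[, te, drop = FALSE])
  }
  list(probs = probs, fold = stats::setNames(fold, names(y)))
}

# Group sample ids by the two-sided confidence rule: -1 group is
# probability in [0, c) (half-open: a probability of exactly c is NOT
# confident), +1 group is [1-c, 1].
confident_groups <- function(probs, c) {
  list(
    neg = names(probs)[probs < c],
    pos = names(probs)[probs >= 1 - c]
  )
}

#' Five-arm overlap experiment: how reliable are predicted labels in DGEA?
#'
#' Samples are split into `folds` stratified folds.  In each rotation one
#' fold is the evaluation set (Dataset2), the next fold plays the role of a
#' newly collected dataset (Dataset3), and the remaining folds are the
#' training set (Dataset1).  The reference gene list DEG1 comes from a
#' fold-sized class-ratio-preserving subsample of Dataset1.  Five gene
#' lists are then compared with DEG1 by overlap count: Dataset2 with true
#' labels (True), Dataset2 with confident-subset predicted labels under a
#' model trained on Dataset1 for each precision target in `x_list`
#' (PCAP arms), Dataset3 with true labels (CollectNew), and Dataset2 with
#' permuted labels (Random).  Overlap counts are averaged over the
#' rotations, and the whole procedure is repeated `repeats` times with
#' fresh fold assignments.
#'
#' Predicted groups use the two-sided rule with cutoff `two_sided_c`.
#' Supplying `prob_fun(X_train, y_train, X_new)` replaces model training
#' with externally provided probabilities (e.g. an oracle for testing);
#' otherwise the pipeline of `spec` is fitted per rotation.  With a single
#' `spec` the PCAP arms share one fitted model; supplying a list of
#' `candidates` makes each arm select its model by median PCAP_x first.
#'
#' @param X numeric matrix, genes x samples (raw values).
#' @param y named +1/-1 vector of true labels.
#' @param spec a [model_spec()] (ignored when `prob_fun` is given).
#' @param x_list precision targets for the prediction arms.
#' @param folds number of stratified folds; the default design uses 10
#'   (8 training, 1 evaluation, 1 "newly collected").
#' @param repeats number of independent repetitions.
#' @param threshold DEG significance threshold.
#' @param seed integer seed.
#' @param prob_fun optional `function(X_train, y_train, X_new)` returning
#'   probabilities of class +1 for the columns of `X_new`.
#' @param two_sided_c confidence cutoff for predicted groups.
#' @param candidates optional list of [model_spec()] candidates for
#'   per-arm model selection.
#' @param ... further arguments passed to [deg_ttest()].
#' @return data.frame with one row per repeat and one column per arm
#'   (mean overlap count with DEG1 across rotations).
#' @export
fiveway_overlap_experiment <- function(X, y, spec = NULL, x_list = c(95, 90),
                                       folds = 10, repeats = 50,
                                       threshold = 0.05, seed = 1,
                                       prob_fun = NULL, two_sided_c = 0.25,
                                       candidates = NULL, ...) {
  if (is.null(prob_fun) && is.null(spec) && is.null(candidates)) {
    stop("supply a model spec, candidates, or prob_fun")
  }
  arms <- c("true", paste0("pcap", x_list), "collect_new", "random")
  out <- matrix(NA_real_, repeats, length(arms),
                dimnames = list(NULL, arms))
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, derive_seed(seed, 401, r))
    acc <- matrix(NA_real_, folds, length(arms),
                  dimnames = list(NULL, arms))
    for (i in seq_len(folds)) {
      i3 <- if (i == folds) 1L else i + 1L
      s2 <- names(y)[fold == i]
      s3 <- names(y)[fold == i3]
      s1 <- names(y)[fold != i & fold != i3]
      y1 <- y[s1]; y2 <- y[s2]; y3 <- y[s3]

      # DEG1: fold-sized subsample of Dataset1 keeping the class ratio
      sub <- withr_seed(derive_seed(seed, 402, r, i), {
        unlist(lapply(c(1, -1), function(cl) {
          ids <- names(y1)[y1 == cl]
          n_take <- max(2L, min(length(ids), sum(y2 == cl)))
          sample(ids, n_take)
        }))
      })
      ysub <- y[sub]
      deg1 <- deg_ttest(X, names(ysub)[ysub == 1], names(ysub)[ysub == -1],
                        threshold = threshold, ...)

      deg2_t <- deg_ttest(X, s2[y2 == 1], s2[y2 == -1],
                          threshold = threshold, ...)
      acc[i, "true"] <- deg_overlap(deg1, deg2_t)$n_overlap

      deg3 <- deg_ttest(X, s3[y3 == 1], s3[y3 == -1],
                        threshold = threshold, ...)
      acc[i, "collect_new"] <- deg_overlap(deg1, deg3)$n_overlap

      yr <- withr_seed(derive_seed(seed, 403, r, i), {
        stats::setNames(sample(y2), s2)
      })
      deg2_r <- deg_ttest(X, s2[yr == 1], s2[yr == -1],
                          threshold = threshold, ...)
      acc[i, "random"] <- deg_overlap(deg1, deg2_r)$n_overlap

      for (m in seq_along(x_list)) {
        xm <- x_list[m]
        probs <- if (!is.null(prob_fun)) {
          prob_fun(X[, s1, drop = FALSE], y1, X[, s2, drop = FALSE])
        } else {
          sp <- if (!is.null(candidates)) {
            select_model(candidates, X[, s1, drop = FALSE], y1,
                         criterion = "pcap", x = xm,
                         outer_folds = min(5, min(table(y1))),
                         inner_folds = min(5, min(table(y1)) - 1),
                         seed = derive_seed(seed, 404, r, i, m))$best_spec
          } else {
            spec
          }
          pl <- fit_pipeline(X[, s1, drop = FALSE], y1, sp,
                             seed = derive_seed(seed, 405, r, i, m))
          predict(pl, X[, s2, drop = FALSE])
        }
        names(probs) <- s2
        grp <- confident_groups(probs, two_sided_c)
        arm <- paste0("pcap", xm)
        if (length(grp$pos) >= 2 && length(grp$neg) >= 2) {
          deg2_p <- deg_ttest(X, grp$pos, grp$neg, threshold = threshold, ...)
          acc[i, arm] <- deg_overlap(deg1, deg2_p)$n_overlap
        }
      }
    }
    out[r, ] <- colMeans(acc, na.rm = TRUE)
  }
  as.data.frame(out)
}

#' Sweep the two-sided confidence cutoff in predicted-label DGEA
#'
#' The reference list DEG_t uses all samples with their true labels.  For
#' every cutoff `c` and fold, the fold's samples are grouped by the
#' two-sided rule (probability in \[0, c) vs \[1-c, 1\]; the middle band is
#' dropped) and the resulting gene list's percent overlap with DEG_t is
#' recorded.  Cells where either group has fewer than 2 samples are
#' undefined and excluded from the medians.
#'
#' @param X numeric matrix, genes x samples (raw values).
#' @param y named +1/-1 vector of true labels.
#' @param probs named out-of-fold probabilities (e.g. from
#'   [cv_probabilities()] or an oracle).
#' @param fold named fold ids aligned with `probs`.
#' @param c_grid cutoffs to sweep.
#' @param threshold DEG significance threshold.
#' @param ... further arguments passed to [deg_ttest()].
#' @return list with `table` (data.frame: c, fold, percent), `median_by_c`,
#'   `best_c` (smallest c maximizing the median) and `best_median`.
#' @export
cutoff_sweep <- function(X, y, probs, fold, c_grid = seq(0.05, 0.5, 0.05),
                         threshold = 0.05, ...) {
  stopifnot(!is.null(names(probs)), !is.null(names(fold)))
  deg_t <- deg_ttest(X, names(y)[y == 1], names(y)[y == -1],
                     threshold = threshold, ...)
  rows <- list()
  for (cc in c_grid) {
    for (f in sort(unique(fold))) {
      ids <- names(fold)[fold == f]
      grp <- confident_groups(probs[ids], cc)
      pct <- NA_real_
      if (length(grp$pos) >= 2 && length(grp$neg) >= 2) {
        deg_p <- deg_ttest(X, grp$pos, grp$neg, threshold = threshold, ...)
        pct <- deg_overlap(deg_t, deg_p)$percent
      }
      rows[[length(rows) + 1]] <- data.frame(c = cc, fold = f, percent = pct)
    }
  }
  tab <- do.call(rbind, rows)
  med <- vapply(c_grid, function(cc) {
    stats::median(tab$percent[tab$c == cc], na.rm = TRUE)
  }, numeric(1))
  names(med) <- as.character(c_grid)
  ok <- !is.na(med)
  best_c <- if (any(ok)) c_grid[ok][which.max(med[ok])] else NA_real_
  list(table = tab, median_by_c = med, best_c = best_c,
       best_median = if (any(ok)) max(med[ok]) else NA_real_)
}
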