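# Proportion of Cases Accurately Predicted (PCAP).
#
# PCAP_x is the fraction of samples whose label can be predicted at a
# precision of at least x%.  It is estimated by nested cross-validation: an
# inner k-fold CV sweeps probability-percentile cutoffs (50..99) over each
# validation fold, the smallest percentile reaching x% precision in the
# most folds becomes the fold's cutoff, and the mean recall at that cutoff
# is the PCAP estimate.  The outer CV then measures the precision actually
# achieved when the calibrated cutoff is applied to unseen data.

PERCENTILE_GRID <- 50:99

#' Precision and recall at a probability-percentile cutoff
#'
#' The threshold is the `p`-th percentile (linear-interpolation definition)
#' of `probs`; samples with probability at or above it are predicted +1.
#'
#' @param probs numeric probabilities of class +1.
#' @param labels true +1/-1 vector aligned with `probs`.
#' @param p percentile in \[0, 100\] (the calibration grid uses 50..99).
#' @return list with `precision` (NA if nothing is predicted positive, 0 if
#'   positives are predicted but none are true), `recall` (0 when there are
#'   no true positives), `threshold`, `n_pred` and `n_pos`.
#' @export
precision_recall_at_percentile <- function(probs, labels, p) {
  if (length(probs) == 0) stop("empty input")
  if (length(probs) != length(labels)) stop("probs and labels must align")
  t <- pctl(probs, p)
  pred <- probs >= t
  tp <- sum(pred & labels == 1)
  n_pred <- sum(pred)
  n_pos <- sum(labels == 1)
  list(
    precision = if (n_pred == 0) NA_real_ else tp / n_pred,
    recall = if (n_pos == 0) 0 else tp / n_pos,
    threshold = t, n_pred = n_pred, n_pos = n_pos
  )
}

# Precision/recall across the whole percentile grid; returns a list of two
# numeric vectors indexed like `grid`.
pr_grid <- function(probs, labels, grid = PERCENTILE_GRID) {
  prec <- rec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    r <- precision_recall_at_percentile(probs, labels, grid[i])
    prec[i] <- r$precision
    rec[i] <- r$recall
  }
  list(precision = prec, recall = rec, n_pos = sum(labels == 1))
}

#' Select the percentile cutoff reaching a target precision
#'
#' Each percentile is marked 1 in a fold when its precision there is at
#' least `x`%.  The smallest percentile with the largest number of 1s
#' across folds is selected, and the mean recall at it (over folds that
#' contain at least one true positive) is returned.  When no percentile
#' reaches the target in any fold, percentile 99 is returned with
#' `attainable = FALSE` and recall 0.
#'
#' @param precisions k x |grid| matrix of per-fold precisions.
#' @param recalls k x |grid| matrix of per-fold recalls.
#' @param x target precision in percent (e.g. 90 or 95).
#' @param n_pos optional per-fold count of true positives; folds with none
#'   are dropped from the recall mean.
#' @param grid percentile grid (columns of the matrices).
#' @return list with `percentile`, `recall`, `attainable` and the per-grid
#'   `counts`.
#' @export
select_cutoff_percentile <- function(precisions, recalls, x, n_pos = NULL,
                                     grid = PERCENTILE_GRID) {
  precisions <- rbind(precisions)
  recalls <- rbind(recalls)
  stopifnot(ncol(precisions) == length(grid),
            all(dim(precisions) == dim(recalls)))
  hit <- !is.na(precisions) & precisions >= x / 100
  counts <- colSums(hit)
  if (max(counts) == 0) {
    return(list(percentile = max(grid), recall = 0, attainable = FALSE,
                counts = counts))
  }
  sel <- grid[which(counts == max(counts))[1]]
  keep <- if (is.null(n_pos)) rep(TRUE, nrow(recalls)) else n_pos > 0
  rec <- if (!any(keep)) 0 else mean(recalls[keep, which(grid == sel)])
  list(percentile = sel, recall = rec, attainable = TRUE, counts = counts)
}

#' Estimate PCAP_x by nested cross-validation
#'
#' For each outer fold, an inner `inner_folds`-fold CV on the outer
#' training set refits the full pipeline per fold, sweeps the percentile
#' grid over each validation fold, and selects the fold's cutoff percentile
#' P_i and recall R_i via [select_cutoff_percentile()].  The pipeline is
#' then refitted on the whole outer training set and P_i is applied as a
#' percentile of the outer test fold's own probability distribution to
#' record the precision actually achieved on unseen data.  The PCAP_x
#' estimate is the mean of the R_i (folds where the target precision was
#' unattainable contribute 0), and the deployment cutoff is the mean of the
#' P_i rounded to the nearest grid percentile.
#'
#' Several targets `x` can be estimated in one run; they share every fold,
#' fit and probability and differ only in cutoff selection.
#'
#' @param X numeric matrix, genes x samples (raw values).
#' @param y named +1/-1 vector.
#' @param spec a [model_spec()].
#' @param x target precision(s) in percent.
#' @param outer_folds,inner_folds fold counts of the nested CV.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return object of class `pcap_estimate`; see Details.  Key elements:
#'   `pcap` (named by x), `cutoff` (deployment percentile, named by x),
#'   `percentile`/`inner_recall`/`attainable`/`achieved_precision`/
#'   `achieved_recall` (outer-fold x target matrices), `fold_auroc` and
#'   `fold_f1` (per-outer-fold mean inner-validation AUROC / F1 at 0.5,
#'   reused for model selection under alternative criteria).
#' @export
estimate_pcap <- function(X, y, spec, x = 90, outer_folds = 10,
                          inner_folds = 10, seed = spec$seed) {
  if (is.null(names(y))) stop("y must be named by sample id")
  counts <- table(y)
  if (min(counts) < outer_folds) {
    stop(sprintf(
      "smallest class has %d samples; stratified %d-fold CV needs at least %d",
      min(counts), outer_folds, outer_folds
    ))
  }
  grid <- PERCENTILE_GRID
  ofold <- stratified_folds(y, outer_folds, derive_seed(seed, 101))
  nx <- length(x)
  P <- R <- AP <- AR <- matrix(NA_real_, outer_folds, nx,
                               dimnames = list(NULL, paste0("pcap", x)))
  att <- matrix(TRUE, outer_folds, nx, dimnames = dimnames(P))
  fold_auroc <- fold_f1 <- rep(NA_real_, outer_folds)

  for (i in seq_len(outer_folds)) {
    tr <- names(y)[ofold != i]
    te <- names(y)[ofold == i]
    ifold <- stratified_folds(y[tr], inner_folds, derive_seed(seed, 102, i))
    prec <- rec <- matrix(NA_real_, inner_folds, length(grid))
    npos <- integer(inner_folds)
    in_auroc <- in_f1 <- rep(NA_real_, inner_folds)
    for (j in seq_len(inner_folds)) {
      itr <- tr[ifold != j]
      ival <- tr[ifold == j]
      pl <- fit_pipeline(X[, itr, drop = FALSE], y[itr], spec,
                         seed = derive_seed(seed, 103, i, j))
      pv <- predict(pl, X[, ival, drop = FALSE])
      g <- pr_grid(pv, y[ival], grid)
      prec[j, ] <- g$precision
      rec[j, ] <- g$recall
      npos[j] <- g$n_pos
      if (length(unique(y[ival])) == 2) in_auroc[j] <- auroc(y[ival], pv)
      in_f1[j] <- f1_score(y[ival], ifelse(pv >= 0.5, 1, -1))
    }
    fold_auroc[i] <- mean(in_auroc, na.rm = TRUE)
    fold_f1[i] <- mean(in_f1, na.rm = TRUE)

    pl_o <- fit_pipeline(X[, tr, drop = FALSE], y[tr], spec,
                         seed = derive_seed(seed, 104, i))
    pt <- predict(pl_o, X[, te, drop = FALSE])
    for (m in seq_len(nx)) {
      sel <- select_cutoff_percentile(prec, rec, x[m], n_pos = npos,
                                      grid = grid)
      P[i, m] <- sel$percentile
      R[i, m] <- if (sel$attainable) sel$recall else 0
      att[i, m] <- sel$attainable
      a <- precision_recall_at_percentile(pt, y[te], sel$percentile)
      AP[i, m] <- a$precision
      AR[i, m] <- a$recall
    }
  }

  structure(
    list(
      x = x, spec = spec, outer_folds = outer_folds,
      inner_folds = inner_folds, seed = seed,
      percentile = P, inner_recall = R, attainable = att,
      achieved_precision = AP, achieved_recall = AR,
      pcap = colMeans(R),
      cutoff = stats::setNames(
        pmin(max(grid), pmax(min(grid), round(colMeans(P)))), colnames(P)
      ),
      fold_auroc = fold_auroc, fold_f1 = fold_f1,
      fold_assignment = stats::setNames(ofold, names(y))
    ),
    class = "pcap_estimate"
  )
}

#' @export
print.pcap_estimate <- function(x, ...) {
  cat(sprintf("PCAP estimate (%d outer x %d inner folds)\n",
              x$outer_folds, x$inner_folds))
  for (m in seq_along(x$x)) {
    cat(sprintf(
      "  PCAP_%d = %.3f  (deployment cutoff percentile %d, mean achieved test precision %.3f)\n",
      x$x[m], x$pcap[m], x$cutoff[m],
      mean(x$achieved_precision[, m], na.rm = TRUE)
    ))
  }
  invisible(x)
}

#' Select among candidate model specifications
#'
#' Runs [estimate_pcap()] for every candidate on identical folds and picks
#' the winner by the median across outer folds of the chosen criterion:
#' per-fold PCAP_x (`"pcap"`), mean inner-validation F1 (`"f1"`) or AUROC
#' (`"auroc"`).  The median (not the maximum) is used so one lucky fold
#' cannot promote an unstable candidate.  Ties keep the earliest candidate.
#'
#' @param candidates list of [model_spec()] objects.
#' @param X,y data as for [estimate_pcap()].
#' @param criterion `"pcap"`, `"f1"` or `"auroc"`.
#' @param x target precision(s); the first is the selection target when
#'   `criterion = "pcap"`.
#' @param outer_folds,inner_folds fold counts.
#' @param seed integer seed shared by all candidates.
#' @return list with `best_spec`, `best_index`, `criterion_medians`,
#'   `report` (per candidate x fold criterion values) and `estimates`.
#' @export
select_model <- function(candidates, X, y, criterion = c("pcap", "f1", "auroc"),
                         x = 90, outer_folds = 10, inner_folds = 10,
                         seed = 1) {
  criterion <- match.arg(criterion)
  if (!length(candidates)) stop("need at least one candidate")
  if (inherits(candidates, "model_spec")) candidates <- list(candidates)
  estimates <- lapply(candidates, function(sp) {
    estimate_pcap(X, y, sp, x = x, outer_folds = outer_folds,
                  inner_folds = inner_folds, seed = seed)
  })
  per_fold <- vapply(estimates, function(e) {
    switch(criterion,
      pcap = e$inner_recall[, 1],
      f1 = e$fold_f1,
      auroc = e$fold_auroc
    )
  }, numeric(outer_folds))
  per_fold <- matrix(per_fold, nrow = outer_folds)
  meds <- apply(per_fold, 2, stats::median, na.rm = TRUE)
  best <- median_winner(t(per_fold))
  list(
    best_spec = candidates[[best]], best_index = best,
    criterion = criterion, criterion_medians = meds,
    report = t(per_fold), estimates = estimates
  )
}

#' Pick the winning candidate by median per-fold score
#'
#' The candidate whose per-fold scores have the largest median wins; using
#' the median rather than the maximum keeps one lucky fold from promoting
#' an unstable candidate.  Ties keep the earliest candidate.
#'
#' @param report candidates x folds numeric matrix of per-fold scores.
#' @return index of the winning row.
#' @export
median_winner <- function(report) {
  meds <- apply(rbind(report), 1, stats::median, na.rm = TRUE)
  unname(which(meds == max(meds))[1])
}

#' Calibrate a deployable model on a full training set
#'
#' Runs a single-level stratified k-fold CV to select the cutoff percentile
#' for the target precision (as in the inner loop of [estimate_pcap()]),
#' then refits the pipeline on all of the data.  The result can make
#' confident-subset predictions on new samples.
#'
#' @param X,y training data as for [fit_pipeline()].
#' @param spec a [model_spec()].
#' @param x target precision in percent.
#' @param folds calibration folds.
#' @param seed integer seed.
#' @return object of class `pcap_calibrated`: the fitted pipeline plus
#'   `cutoff` (percentile), `x`, `attainable` and the estimated recall
#'   (`pcap`).
#' @export
calibrate_model <- function(X, y, spec, x = 90, folds = 10,
                            seed = spec$seed) {
  grid <- PERCENTILE_GRID
  fold <- stratified_folds(y, folds, derive_seed(seed, 201))
  prec <- rec <- matrix(NA_real_, folds, length(grid))
  npos <- integer(folds)
  val_probs <- vector("list", folds)
  for (j in seq_len(folds)) {
    itr <- names(y)[fold != j]
    ival <- names(y)[fold == j]
    pl <- fit_pipeline(X[, itr, drop = FALSE], y[itr], spec,
                       seed = derive_seed(seed, 202, j))
    pv <- predict(pl, X[, ival, drop = FALSE])
    val_probs[[j]] <- pv
    g <- pr_grid(pv, y[ival], grid)
    prec[j, ] <- g$precision
    rec[j, ] <- g$recall
    npos[j] <- g$n_pos
  }
  sel <- select_cutoff_percentile(prec, rec, x, n_pos = npos, grid = grid)
  # absolute-probability reading of the cutoff: the selected percentile of
  # each calibration fold's probabilities, averaged over folds
  abs_threshold <- mean(vapply(val_probs, pctl, numeric(1), sel$percentile))
  pipeline <- fit_pipeline(X, y, spec, seed = derive_seed(seed, 203))
  structure(
    list(pipeline = pipeline, cutoff = sel$percentile,
         abs_threshold = abs_threshold, x = x,
         pcap = if (sel$attainable) sel$recall else 0,
         attainable = sel$attainable, seed = seed),
    class = "pcap_calibrated"
  )
}

#' Confident-subset prediction
#'
#' One-sided mode (default) thresholds at the calibrated percentile of the
#' new samples' own probability distribution: samples at or above it are
#' labeled +1, the rest abstain.  With `threshold = "absolute"` the
#' calibration folds' probability value at the selected percentile is
#' frozen instead and applied as-is, which is preferable when the new
#' cohort's class prevalence may differ from the calibration cohort's.
#' Two-sided mode (used for downstream group comparisons) labels +1 when
#' the probability is at least `1 - c`, -1 when it is below `c`, and
#' abstains on the middle band; `c = 0.5` labels everything.
#'
#' @param model a `pcap_calibrated` object (two-sided mode also accepts a
#'   plain `pcap_pipeline`).
#' @param X_new numeric matrix, genes x samples (raw values).
#' @param mode `"one-sided"` or `"two-sided"`.
#' @param c two-sided confidence cutoff in (0, 0.5].
#' @param threshold one-sided thresholding rule: `"percentile"` (of the
#'   new samples' own probabilities) or `"absolute"` (frozen from
#'   calibration).
#' @return data.frame with `sample_id`, `probability`, `label` (+1, -1 or
#'   NA for abstain).
#' @export
predict_confident <- function(model, X_new, mode = c("one-sided", "two-sided"),
                              c = 0.25,
                              threshold = c("percentile", "absolute")) {
  mode <- match.arg(mode)
  threshold <- match.arg(threshold)
  pipeline <- if (inherits(model, "pcap_calibrated")) model$pipeline else model
  probs <- predict(pipeline, X_new)
  if (mode == "one-sided") {
    if (!inherits(model, "pcap_calibrated")) {
      stop("one-sided prediction needs a calibrated model")
    }
    t <- if (threshold == "absolute") model$abs_threshold
         else pctl(probs, model$cutoff)
    label <- ifelse(probs >= t, 1, NA_real_)
  } else {
    if (c <= 0 || c > 0.5) stop("c must be in (0, 0.5]")
    label <- rep(NA_real_, length(probs))
    label[probs >= 1 - c] <- 1
    label[probs < c] <- -1
  }
  data.frame(sample_id = names(probs), probability = unname(probs),
             label = label, stringsAsFactors = FALSE, row.names = NULL)
}
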