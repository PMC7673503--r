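# Classifier families, randomized hyperparameter tuning, probability
# predictions, and the standard evaluation metrics.
#
# Four algorithms are supported: L1-penalized logistic regression (glmnet),
# random forest (ranger), gradient-boosted trees (xgboost) and a support
# vector machine (e1071, with built-in Platt probability calibration).

ALGORITHMS <- c("lasso", "rf", "xgb", "svm")

#' Specify one candidate model
#'
#' A "model" is one full pipeline configuration: a learning algorithm, a
#' normalization method, an oversampling switch and a gene-count mode.
#' Model selection compares such specifications against each other.
#'
#' @param algorithm `"lasso"`, `"rf"`, `"xgb"` or `"svm"`.
#' @param normalization `"rank"`, `"rpm"` or `"quantile"`.
#' @param oversample logical; apply SMOTE to the training folds.
#' @param gene_mode `"auto"` (RFE-selected set of at most 100 genes),
#'   `"fixed-10"` or `"fixed-25"`.
#' @param alpha significance level of the Welch gene screen.
#' @param tuning_budget number of random hyperparameter draws.
#' @param tuning_folds folds for hyperparameter-tuning CV.
#' @param rfe_step fraction of genes dropped per RFE iteration.
#' @param rfe_folds folds for the auto-mode RFE score.
#' @param smote_k SMOTE neighbour count.
#' @param search_space optional per-algorithm search space overriding
#'   [default_search_space()].
#' @param seed integer seed; together with the data it fully determines the
#'   fitted model.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm = "lasso",
                       normalization = c("rank", "rpm", "quantile"),
                       oversample = FALSE,
                       gene_mode = c("auto", "fixed-10", "fixed-25"),
                       alpha = 0.1, tuning_budget = 10, tuning_folds = 3,
                       rfe_step = 0.1, rfe_folds = 3, smote_k = 5,
                       search_space = NULL, seed = 1) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  normalization <- match.arg(normalization)
  gene_mode <- match.arg(gene_mode)
  stopifnot(tuning_budget >= 1, tuning_folds >= 2)
  structure(
    list(
      algorithm = algorithm, normalization = normalization,
      oversample = isTRUE(oversample), gene_mode = gene_mode,
      alpha = alpha, tuning_budget = as.integer(tuning_budget),
      tuning_folds = as.integer(tuning_folds), rfe_step = rfe_step,
      rfe_folds = as.integer(rfe_folds), smote_k = as.integer(smote_k),
      search_space = search_space, seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "Model spec: %s / %s%s / genes %s (screen alpha %.2g, %d tuning draws)\n",
    x$algorithm, x$normalization, if (x$oversample) " + SMOTE" else "",
    x$gene_mode, x$alpha, x$tuning_budget
  ))
  invisible(x)
}

#' Default randomized hyperparameter search spaces
#'
#' Each entry describes the distribution a tuning draw samples from:
#' `loguniform` entries are sampled as 10^U(log10 lo, log10 hi), `uniform`
#' as U(lo, hi) (rounded when `integer`), and `choice` uniformly from a set.
#'
#' @param algorithm one of `"lasso"`, `"rf"`, `"xgb"`, `"svm"`.
#' @return named list of parameter descriptors.
#' @export
default_search_space <- function(algorithm) {
  switch(algorithm,
    lasso = list(
      # above ~1 the L1 penalty zeroes every coefficient on data of this
      # scale, so the upper bound stays at 1
      lambda = list(kind = "loguniform", lo = 1e-4, hi = 1e0)
    ),
    rf = list(
      num.trees = list(kind = "uniform", lo = 100, hi = 1000, integer = TRUE),
      max.depth = list(kind = "uniform", lo = 2, hi = 10, integer = TRUE),
      mtry_frac = list(kind = "uniform", lo = 0.05, hi = 0.8)
    ),
    xgb = list(
      nrounds = list(kind = "uniform", lo = 100, hi = 1000, integer = TRUE),
      max_depth = list(kind = "uniform", lo = 2, hi = 10, integer = TRUE),
      eta = list(kind = "loguniform", lo = 0.01, hi = 0.3),
      subsample = list(kind = "uniform", lo = 0.5, hi = 1)
    ),
    svm = list(
      cost = list(kind = "loguniform", lo = 1e-3, hi = 1e3),
      kernel = list(kind = "choice", values = c("linear", "radial")),
      gamma = list(kind = "loguniform", lo = 1e-3, hi = 1e1)
    ),
    stop("unknown algorithm: ", algorithm)
  )
}

# Fixed mid-range parameters used for RFE importance fits (a single cheap
# fit, no tuning).
default_params <- function(algorithm, n_features) {
  switch(algorithm,
    lasso = list(lambda = 0.01),
    rf = list(num.trees = 300, max.depth = 0,
              mtry_frac = NA),
    xgb = list(nrounds = 100, max_depth = 4, eta = 0.1, subsample = 1),
    svm = list(cost = 1, kernel = "linear", gamma = 1 / max(1, n_features))
  )
}

# Draw n random hyperparameter sets from the search space.
draw_hyperparams <- function(algorithm, n, seed, search_space = NULL) {
  space <- search_space %||% default_search_space(algorithm)
  draws <- vector("list", n)
  withr_seed(seed, {
    for (i in seq_len(n)) {
      params <- list()
      for (nm in names(space)) {
        d <- space[[nm]]
        params[[nm]] <- switch(d$kind,
          loguniform = 10^stats::runif(1, log10(d$lo), log10(d$hi)),
          uniform = {
            v <- stats::runif(1, d$lo, d$hi)
            if (isTRUE(d$integer)) round(v) else v
          },
          choice = d$values[sample.int(length(d$values), 1)],
          stop("unknown search-space kind: ", d$kind)
        )
      }
      draws[[i]] <- params
    }
  })
  draws
}

# ---- low-level fit/predict per algorithm --------------------------------

# y is +1/-1; internally classes become a factor with levels c("neg","pos")
# and all probabilities refer to "pos" (= +1).
as_class_factor <- function(y) {
  factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
}

fit_classifier <- function(X, y, algorithm, params, seed = 1,
                           importance = FALSE) {
  if (length(unique(y)) < 2) stop("training data contains a single class")
  yf <- as_class_factor(y)
  pad <- FALSE
  model <- switch(algorithm,
    lasso = {
      # short warm-start path ending at the target lambda keeps glmnet
      # stable with a single effective penalty
      lam <- params$lambda
      Xl <- X
      if (ncol(Xl) < 2) {
        # glmnet requires >= 2 columns; pad with a constant that can never
        # be selected
        Xl <- cbind(Xl, `.pad.` = 0)
        pad <- TRUE
      }
      # cross-validation folds can be tiny; glmnet's small-class warning is
      # expected there and not actionable
      m <- suppressWarnings(
        glmnet::glmnet(Xl, yf, family = "binomial", alpha = 1,
                       lambda = c(lam * 8, lam * 3, lam))
      )
      if (!length(m$lambda) || any(!is.finite(m$lambda))) {
        # the solver can bail out on a user path whose smallest lambda is
        # unreachable; fall back to its own path and predict at s = lambda
        # (clamped into the path range)
        m <- suppressWarnings(
          glmnet::glmnet(Xl, yf, family = "binomial", alpha = 1,
                         nlambda = 30)
        )
      }
      m
    },
    rf = {
      mtry <- if (is.na(params$mtry_frac %||% NA)) {
        max(1L, floor(sqrt(ncol(X))))
      } else {
        max(1L, ceiling(params$mtry_frac * ncol(X)))
      }
      ranger::ranger(
        x = X, y = yf, num.trees = params$num.trees,
        mtry = min(mtry, ncol(X)), max.depth = params$max.depth,
        probability = TRUE, seed = seed, num.threads = 1,
        importance = if (importance) "impurity" else "none"
      )
    },
    xgb = {
      xgboost::xgboost(
        x = X, y = yf, objective = "binary:logistic",
        nrounds = params$nrounds, max_depth = params$max_depth,
        learning_rate = params$eta, subsample = params$subsample,
        nthreads = 1, seed = seed, verbosity = 0
      )
    },
    svm = {
      withr_seed(seed, {
        e1071::svm(
          x = X, y = yf, kernel = params$kernel, cost = params$cost,
          gamma = if (identical(params$kernel, "radial")) params$gamma
                  else 1 / max(1, ncol(X)),
          probability = TRUE, scale = apply(X, 2, stats::sd) > 0
        )
      })
    },
    stop("unknown algorithm: ", algorithm)
  )
  structure(
    list(algorithm = algorithm, params = params, model = model,
         features = colnames(X), seed = seed, pad = pad),
    class = "pcap_classifier"
  )
}

classifier_predict <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  p <- switch(fit$algorithm,
    lasso = {
      Xl <- if (isTRUE(fit$pad)) cbind(X, `.pad.` = 0) else X
      as.vector(stats::predict(fit$model, newx = Xl,
                               s = fit$params$lambda, type = "response"))
    },
    rf = stats::predict(fit$model, data = X,
                        num.threads = 1)$predictions[, "pos"],
    xgb = stats::predict(fit$model, X),  # P(second level) = P(pos)
    svm = {
      pr <- stats::predict(fit$model, X, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    }
  )
  p <- pmin(1, pmax(0, as.numeric(p)))
  names(p) <- rownames(X)
  p
}

classifier_importance <- function(fit) {
  imp <- switch(fit$algorithm,
    lasso = {
      co <- stats::coef(fit$model, s = fit$params$lambda)
      v <- abs(as.numeric(co)[-1])
      names(v) <- rownames(co)[-1]
      v[names(v) != ".pad."]
    },
    rf = ranger::importance(fit$model),
    xgb = {
      tab <- xgboost::xgb.importance(model = fit$model)
      v <- stats::setNames(rep(0, length(fit$features)), fit$features)
      if (nrow(tab)) v[tab$Feature] <- tab$Gain
      v
    },
    svm = {
      if (identical(fit$params$kernel, "linear")) {
        w <- t(fit$model$coefs) %*% fit$model$SV
        stats::setNames(abs(as.numeric(w)), colnames(fit$model$SV))
      } else {
        # no native importance for non-linear kernels: use the magnitude of
        # the class-mean difference in the (scaled) feature space
        stats::setNames(rep(1, length(fit$features)), fit$features)
      }
    }
  )
  out <- stats::setNames(rep(0, length(fit$features)), fit$features)
  out[names(imp)] <- imp
  out
}

# ---- tuning --------------------------------------------------------------

#' Tune hyperparameters and fit a classifier
#'
#' Draws `spec$tuning_budget` random hyperparameter sets from the
#' algorithm's search space, scores each by mean AUROC over a stratified
#' `spec$tuning_folds`-fold cross-validation of the training data, and
#' refits the best draw (ties: first) on all of it.
#'
#' @param X numeric matrix, samples x genes (the selected feature set).
#' @param y +1/-1 vector aligned with rows of `X`.
#' @param spec a [model_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return object of class `pcap_fit` wrapping the winning classifier, its
#'   hyperparameters and the per-draw CV scores.
#' @export
tune_and_fit <- function(X, y, spec, seed = spec$seed) {
  if (length(unique(y)) < 2) stop("training data contains a single class")
  draws <- draw_hyperparams(spec$algorithm, spec$tuning_budget,
                            derive_seed(seed, 1), spec$search_space)
  k <- min(spec$tuning_folds, min(table(y)))
  scores <- rep(NA_real_, length(draws))
  if (k >= 2) {
    fold <- stratified_folds(y, k, derive_seed(seed, 2))
    for (i in seq_along(draws)) {
      fs <- c()
      for (f in sort(unique(fold))) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
        fit <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec$algorithm,
                              draws[[i]], seed = derive_seed(seed, 3, i, f))
        fs <- c(fs, auroc(y[!tr],
                          classifier_predict(fit, X[!tr, , drop = FALSE])))
      }
      if (length(fs)) scores[i] <- mean(fs)
    }
  }
  best <- if (all(is.na(scores))) 1L else which.max(scores)
  fit <- fit_classifier(X, y, spec$algorithm, draws[[best]],
                        seed = derive_seed(seed, 4))
  structure(
    list(spec = spec, classifier = fit, params = draws[[best]],
         features = colnames(X), cv_scores = scores, seed = seed),
    class = "pcap_fit"
  )
}

#' Predict class-+1 probabilities
#'
#' @param fit a `pcap_fit` from [tune_and_fit()].
#' @param X_new numeric matrix, samples x genes; must contain every gene of
#'   the model's feature set (extra genes and arbitrary column order are
#'   fine — alignment is by gene id).
#' @return named numeric vector of probabilities of class +1, in \[0, 1\].
#' @export
predict_proba <- function(fit, X_new) {
  missing_g <- setdiff(fit$features, colnames(X_new))
  if (length(missing_g)) {
    stop("missing required gene(s): ", paste(missing_g, collapse = ", "))
  }
  classifier_predict(fit$classifier, X_new[, fit$features, drop = FALSE])
}

# ---- metrics -------------------------------------------------------------

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen +1 sample receives a higher
#' score than a uniformly chosen -1 sample, counting ties as 1/2
#' (rank-based Mann-Whitney formulation).
#'
#' @param labels +1/-1 vector.
#' @param probs numeric scores aligned with `labels`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, probs) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score for the positive (+1) class
#'
#' Harmonic mean of precision and recall for class +1; 0 when there are no
#' true positives (including when nothing is predicted positive).
#'
#' @param labels true +1/-1 vector.
#' @param predicted predicted +1/-1 vector.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(labels, predicted) {
  tp <- sum(labels == 1 & predicted == 1)
  fp <- sum(labels == -1 & predicted == 1)
  fn <- sum(labels == 1 & predicted == -1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
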