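# End-to-end training pipeline for one model specification.
#
# All data-dependent stages (normalization reference, gene screen, RFE,
# SMOTE, hyperparameter tuning) are fitted on training samples only and
# replayed on new samples at prediction time, so cross-validation estimates
# are leakage-free.  Stage order inside a training set: normalize ->
# Welch screen -> RFE -> SMOTE -> tune/fit.

#' Fit the full prediction pipeline on a training set
#'
#' @param X numeric matrix, genes x samples (raw values).
#' @param y named +1/-1 vector; names must be columns of `X`.
#' @param spec a [model_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return object of class `pcap_pipeline` holding the normalization state,
#'   screen results, selected features and fitted classifier.
#' @export
fit_pipeline <- function(X, y, spec, seed = spec$seed) {
  if (is.null(names(y))) stop("y must be named by sample id")
  X <- X[, names(y), drop = FALSE]

  quantile_ref <- NULL
  if (spec$normalization == "quantile") {
    quantile_ref <- quantile_reference(X)
  }
  Xn <- normalize_expression(X, spec$normalization, reference = quantile_ref)

  # zero-variance genes carry no information and break the t statistic
  keep <- apply(Xn, 1, stats::sd) > 0
  screen <- welch_screen(Xn[keep, , drop = FALSE], y, alpha = spec$alpha)
  candidates <- screen$gene_id[screen$pass]
  if (length(candidates) == 0) {
    # degenerate training set: fall back to the smallest p-values so the
    # pipeline still yields a model
    warning("no genes passed screening; using 10 smallest p-values")
    candidates <- screen$gene_id[order(screen$p)][seq_len(min(10, nrow(screen)))]
  }

  Xs <- t(Xn[candidates, , drop = FALSE])
  features <- rfe_select(Xs, y, spec, mode = spec$gene_mode,
                         inner_folds = spec$rfe_folds,
                         seed = derive_seed(seed, 21), step = spec$rfe_step)

  Xf <- Xs[, features, drop = FALSE]
  yf <- y
  if (spec$oversample) {
    aug <- smote_oversample(Xf, yf, k_neighbors = spec$smote_k,
                            seed = derive_seed(seed, 22))
    Xf <- aug$X
    yf <- aug$y
  }

  fit <- tune_and_fit(Xf, yf, spec, seed = derive_seed(seed, 23))

  structure(
    list(spec = spec, fit = fit, features = features, screen = screen,
         quantile_ref = quantile_ref, n_candidates = length(candidates),
         seed = seed),
    class = "pcap_pipeline"
  )
}

#' Predict class-+1 probabilities with a fitted pipeline
#'
#' New samples are normalized with the pipeline's method (per-sample for
#' rank/RPM; against the frozen training reference for quantile) before the
#' classifier is applied.
#'
#' @param object a `pcap_pipeline` from [fit_pipeline()].
#' @param X_new numeric matrix, genes x samples (raw values).
#' @param ... unused.
#' @return named numeric vector of probabilities of class +1.
#' @export
predict.pcap_pipeline <- function(object, X_new, ...) {
  Xn <- normalize_expression(X_new, object$spec$normalization,
                             reference = object$quantile_ref)
  predict_proba(object$fit, t(Xn))
}

#' @export
print.pcap_pipeline <- function(x, ...) {
  cat(sprintf(
    "Fitted pipeline: %s / %s%s; %d screened -> %d selected genes\n",
    x$spec$algorithm, x$spec$normalization,
    if (x$spec$oversample) " + SMOTE" else "",
    x$n_candidates, length(x$features)
  ))
  invisible(x)
}
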