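# Internal helpers: seed derivation, stratified folds, percentile cutoffs.

# Deterministically expand a root seed into per-stage seeds.  Multipliers are
# kept small enough that all arithmetic stays exact in doubles and the result
# fits in a 32-bit integer.
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (v in c(...)) {
    s <- (s * 69069 + as.double(v) * 10007 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` cross-validation folds so that both
#' classes are spread as evenly as possible across folds.
#'
#' @param y vector of class labels coded +1/-1.
#' @param k number of folds.
#' @param seed integer seed controlling the permutation.
#' @return integer vector of fold ids (1..k), aligned with `y`.
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  if (k < 2) stop("need at least 2 folds")
  counts <- table(y)
  if (length(counts) < 2) stop("both classes must be present to stratify")
  if (min(counts) < k) {
    stop(sprintf(
      "smallest class has %d samples; stratified %d-fold CV needs at least %d",
      min(counts), k, k
    ))
  }
  fold <- integer(length(y))
  withr_seed(seed, {
    for (cls in names(counts)) {
      idx <- which(y == as.numeric(cls))
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package internals never disturb user code.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Percentile with the linear-interpolation definition (quantile type 7);
# the same definition is used for calibration and deployment cutoffs.
pctl <- function(x, p) {
  stats::quantile(x, p / 100, type = 7, names = FALSE)
}

# Validate an expression matrix: numeric, non-negative, unique dimnames.
validate_expression <- function(M, what = "expression matrix") {
  if (!is.matrix(M) || !is.numeric(M)) {
    stop(what, " must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop(what, " must have gene ids as rownames and sample ids as colnames")
  }
  dup_g <- unique(rownames(M)[duplicated(rownames(M))])
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(M)[duplicated(colnames(M))])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(M)) stop(what, " contains missing values")
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative value at gene '%s', sample '%s'",
      rownames(M)[bad[1]], colnames(M)[bad[2]]
    ))
  }
  invisible(M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
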