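# Within-sample and between-sample normalization of expression matrices.
#
# Three methods are supported: reads-per-million (sequencing counts),
# quantile normalization (microarray intensities) and rank normalization
# (either platform).  RPM and rank normalization are strictly per-sample;
# quantile normalization learns a reference distribution that can be frozen
# on a training set and applied to new samples.

#' Reads-per-million normalization
#'
#' Scales each sample (column) so its values sum to 10^6.
#'
#' @param M numeric matrix, genes x samples.
#' @return matrix of the same shape with attribute `normalization = "rpm"`.
#' @export
rpm_normalize <- function(M) {
  validate_expression(M)
  totals <- colSums(M)
  zero <- colnames(M)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with all-zero expression: ", paste(zero, collapse = ", "))
  }
  out <- sweep(M, 2, totals, "/") * 1e6
  attr(out, "normalization") <- "rpm"
  out
}

#' Rank normalization
#'
#' Within each sample, every expression value is replaced by its rank (1 =
#' lowest, n = highest; ties receive the average of the tied rank
#' positions), then rescaled by the sum of all ranks n(n+1)/2 and multiplied
#' by 10^6.  Only the within-sample ordering survives, which makes the
#' result comparable across platforms and robust to monotone distortions.
#'
#' @param M numeric matrix, genes x samples.
#' @return matrix of the same shape with attribute `normalization = "rank"`;
#'   every column sums to 10^6.
#' @export
rank_normalize <- function(M) {
  validate_expression(M)
  n <- nrow(M)
  denom <- n * (n + 1) / 2
  out <- apply(M, 2, function(col) rank(col, ties.method = "average")) / denom * 1e6
  if (!is.matrix(out)) out <- matrix(out, nrow = n, dimnames = dimnames(M))
  dimnames(out) <- dimnames(M)
  attr(out, "normalization") <- "rank"
  out
}

#' Quantile-normalization reference distribution
#'
#' The reference is the mean of the sorted per-sample value vectors: entry k
#' is the mean across samples of each sample's k-th smallest value.
#'
#' @param M numeric matrix, genes x samples, at least 2 samples.
#' @return sorted numeric vector of length `nrow(M)`.
#' @export
quantile_reference <- function(M) {
  validate_expression(M)
  if (ncol(M) < 2) stop("quantile normalization needs at least 2 samples")
  rowMeans(apply(M, 2, sort))
}

#' Quantile normalization
#'
#' Replaces the rank-k value of every sample by the mean rank-k value across
#' samples, so that all samples share one empirical distribution.  Ties
#' within a sample receive the mean of the reference values across the tied
#' rank span.  Supplying `reference` (from [quantile_reference()] on a
#' training set) projects new samples onto a frozen training distribution
#' instead of their own, which avoids information leaking from test to
#' training data in cross-validation.
#'
#' @param M numeric matrix, genes x samples.
#' @param reference optional sorted reference vector of length `nrow(M)`.
#' @return matrix of the same shape with attribute `normalization =
#'   "quantile"`.
#' @export
quantile_normalize <- function(M, reference = NULL) {
  validate_expression(M)
  if (is.null(reference)) {
    reference <- quantile_reference(M)
  } else {
    if (length(reference) != nrow(M)) {
      stop("reference length must equal the number of genes")
    }
    reference <- sort(reference)
  }
  out <- apply(M, 2, function(col) {
    rf <- rank(col, ties.method = "first")
    ra <- rank(col, ties.method = "average")
    # each tied group shares one average rank; give every member the mean of
    # the reference values over the group's occupied rank positions
    stats::ave(reference[rf], ra, FUN = mean)
  })
  dimnames(out) <- dimnames(M)
  attr(out, "normalization") <- "quantile"
  out
}

#' Apply one of the three supported normalizations
#'
#' @param M numeric matrix, genes x samples.
#' @param method `"rpm"`, `"quantile"` or `"rank"`.
#' @param reference optional frozen reference distribution (quantile only).
#' @return normalized matrix with a `normalization` attribute.
#' @export
normalize_expression <- function(M, method = c("rank", "rpm", "quantile"),
                                 reference = NULL) {
  method <- match.arg(method)
  switch(method,
    rpm = rpm_normalize(M),
    rank = rank_normalize(M),
    quantile = quantile_normalize(M, reference = reference)
  )
}
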