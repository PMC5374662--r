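#' Quantile normalization
#'
#' Forces every sample (column) onto the common distribution obtained by
#' averaging the sorted value vectors across samples. Ties within a sample
#' receive the mean of the quantile targets they span, so within-sample ranks
#' are preserved.
#'
#' @param x expression matrix with >= 2 samples.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    # non-integer (tied) ranks get the mean of the two flanking targets
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

#' Linear scaling to equal sample totals
#'
#' Multiplies each sample by (mean of all sample totals) / (its own total),
#' so that all column sums are equal afterwards.
#'
#' @param x expression matrix; every sample must have a positive total.
#' @return scaled matrix.
#' @export
linear_scale <- function(x) {
  validate_expression_matrix(x)
  totals <- colSums(x)
  if (any(totals <= 0)) {
    bad <- colnames(x)[totals <= 0][1]
    stop("sample '", bad, "' has non-positive total; cannot scale", call. = FALSE)
  }
  sweep(x, 2, mean(totals) / totals, `*`)
}

#' Apply a named correction method
#'
#' Convenience dispatcher over [quantile_normalize()], [linear_scale()] and
#' [combat_correct()]. The empirical-Bayes method models additive batch
#' effects, so it operates on log2(x + 1) by default and is back-transformed
#' to the abundance scale (clipped at zero).
#'
#' @param x expression matrix (abundance scale).
#' @param meta sample metadata (needed for `"combat"`).
#' @param method one of `"combat"`, `"quantile"`, `"linear"`, `"none"`.
#' @param log2_transform apply the log2(x+1) round-trip for `"combat"`.
#' @param covariate include the class label as covariate in `"combat"`.
#' @return corrected matrix on the abundance scale.
#' @export
correct_batch <- function(x, meta = NULL,
                          method = c("combat", "quantile", "linear", "none"),
                          log2_transform = TRUE, covariate = TRUE) {
  method <- match.arg(method)
  switch(method,
    none = x,
    quantile = quantile_normalize(x),
    linear = linear_scale(x),
    combat = {
      if (is.null(meta)) stop("combat needs sample metadata", call. = FALSE)
      combat_correct(x, meta, log2_transform = log2_transform,
                     covariate = covariate)
    })
}
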