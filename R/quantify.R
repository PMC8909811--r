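#' Transcripts-per-million normalization
#'
#' Length-normalizes a count matrix so that every sample column sums to one
#' million.  For each feature \eqn{i} and sample \eqn{j},
#' \deqn{TPM_{ij} = 10^6 \; \frac{c_{ij}/\ell_i}{\sum_k c_{kj}/\ell_k},}
#' where \eqn{\ell_i} is the feature length in nucleotides.  Mature miRNAs are
#' nearly length-invariant, so miRNA matrices may be normalized with the
#' default unit lengths, in which case TPM is simply counts rescaled per
#' million.
#'
#' @param counts numeric matrix of non-negative counts, features x samples,
#'   with row and column names.
#' @param lengths positive feature lengths in nucleotides, either a named
#'   vector covering all features or `NULL` for unit lengths.
#' @return matrix of TPM values with the dimensions of `counts`.  An all-zero
#'   sample column yields an all-zero TPM column with a warning.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' tpm(m, c(g1 = 100, g2 = 400))  # 800000, 200000
#' @export
tpm <- function(counts, lengths = NULL) {
  check_counts(counts)
  if (is.null(lengths)) {
    lengths <- rep(1, nrow(counts))
  } else {
    if (!is.null(names(lengths))) {
      missing <- setdiff(rownames(counts), names(lengths))
      if (length(missing))
        stop("missing length for feature(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
      lengths <- lengths[rownames(counts)]
    }
    if (length(lengths) != nrow(counts))
      stop("lengths must match the number of features")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("feature lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over features observed
#' in every sample, of the ratio of the sample's count to the feature's
#' geometric mean across samples; factors are rescaled to geometric mean 1.
#' When no feature is nonzero in all samples the function falls back to
#' column-total scaling with a warning.
#'
#' @param counts numeric matrix of non-negative counts, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_counts(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    warning("no feature observed in every sample; using column-total scaling")
    f <- colSums(counts)
    if (any(f == 0)) stop("cannot compute size factors: all-zero sample")
  } else {
    lg <- rowMeans(log(counts[use, , drop = FALSE]))
    f <- apply(counts[use, , drop = FALSE], 2, function(col)
      stats::median(exp(log(col) - lg)))
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# normalized counts: counts divided columnwise by size factors
normalize_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf[colnames(counts)], "/")
}
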