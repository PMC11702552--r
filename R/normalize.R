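#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-of-ratios method:
#' each sample's factor is the median, over reference genes, of that
#' sample's count divided by the gene's geometric mean across samples.
#' Reference genes are those with a non-zero count in every sample.
#' Normalized abundance is `count / size_factor`. Samples here are the
#' timepoint libraries of one genotype: each genotype is normalized
#' within its own sample set.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no reference genes: no gene has all-positive counts")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  factors <- apply(logc, 2, function(col) exp(median(col - loggeo)))
  unname(factors)
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return list with `normalized` (matrix of count / factor) and
#'   `size_factors`.
#' @export
normalize_counts <- function(counts) {
  sf <- size_factors(counts)
  list(normalized = sweep(as.matrix(counts), 2, sf, "/"), size_factors = sf)
}
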