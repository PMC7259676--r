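#' Filter sites on completeness and minor-allele count
#'
#' Reproduces the standard VCF-level site filters applied before
#' population-structure analysis: a site is kept iff its fraction of
#' non-missing genotypes is at least `max_missing` (the VCFtools
#' `--max-missing` convention, despite the name: higher = stricter) and its
#' minor-allele count over non-missing calls is at least `min_mac`. Both
#' boundaries are inclusive, so `min_mac = 3` keeps a site whose minor
#' allele appears exactly 3 times.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Minimum fraction of non-missing genotypes in `[0, 1]`.
#' @param min_mac Minimum minor-allele count (non-negative integer).
#' @return A [genotype_matrix()] with the surviving sites; the sample set is
#'   unchanged. Warns (does not error) if no site survives. Idempotent.
#' @export
filter_sites <- function(g, max_missing = 0.8, min_mac = 3L) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_mac >= 0)
  calls <- g$calls
  n <- nrow(calls)
  n_called <- n - colSums(is.na(calls))
  frac_called <- n_called / n
  alt <- colSums(calls, na.rm = TRUE)
  mac <- pmin(alt, 2L * n_called - alt)
  keep <- frac_called >= max_missing & mac >= min_mac & n_called > 0L
  if (!any(keep)) warning("no sites survive filtering")
  subset_sites(g, keep)
}

#' Thin sites to at most one per distance window
#'
#' Greedy left-to-right per chromosome: the first site of each chromosome is
#' kept, and each later site is kept iff its position is at least
#' `window_bp` beyond the last kept position. Deterministic, matching the
#' "one SNP every N bp" thinning used before MDS/clustering to reduce
#' linkage among markers.
#'
#' @param g A [genotype_matrix()].
#' @param window_bp Minimum spacing in base pairs (> 0).
#' @return A [genotype_matrix()] containing the kept sites.
#' @export
thin_sites <- function(g, window_bp = 10000L) {
  stopifnot(window_bp > 0)
  keep <- logical(n_sites(g))
  for (idx in split(seq_len(n_sites(g)), g$sites$chrom)) {
    last <- -Inf
    for (i in idx) {
      if (g$sites$pos[i] >= last + window_bp) {
        keep[i] <- TRUE
        last <- g$sites$pos[i]
      }
    }
  }
  subset_sites(g, keep)
}
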