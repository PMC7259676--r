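#' Identity-by-state genetic distance between samples
#'
#' For each sample pair, allele sharing per shared non-missing site is 1,
#' 0.5 or 0 as the dosage difference is 0, 1 or 2; the distance is one
#' minus the mean sharing. Pairs with no shared sites are `NA`.
#'
#' @param g A [genotype_matrix()] with >= 2 samples.
#' @return A [pairwise_matrix()] (`statistic = "ibs"`), diagonal 0.
#' @export
ibs_distance <- function(g) {
  if (n_samples(g) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- g$calls
  obs <- (!is.na(x)) * 1
  x0 <- x
  x0[is.na(x0)] <- 0L
  mode(x0) <- "numeric"
  # sum over shared sites of |gi - gj| = gi^2 + gj^2 - 2 gi gj, masked
  sq_obs <- tcrossprod(x0^2, obs)
  cross <- tcrossprod(x0)
  abs_diff_sq <- sq_obs + t(sq_obs) - 2 * cross
  # |gi - gj| in {0,1,2} so |d| = d^2 except d^2=4 -> |d|=2; count d^2=4 pairs
  opp <- tcrossprod((!is.na(x) & x == 0L) * 1, (!is.na(x) & x == 2L) * 1)
  opp <- opp + t(opp)
  sum_abs <- abs_diff_sq - 2 * opp
  n_shared <- tcrossprod(obs)
  d <- sum_abs / (2 * n_shared)
  d[n_shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(g$sample_ids, g$sample_ids)
  pairwise_matrix(d, "ibs")
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson MDS: double-center the squared distance matrix, eigendecompose,
#' and scale the top-`k` eigenvectors by the square roots of their (positive)
#' eigenvalues. Eigenvector sign is arbitrary, so each axis is canonicalized
#' to make its largest-magnitude loading positive; coordinates are therefore
#' deterministic. Negative eigenvalues (non-Euclidean input) are dropped
#' with a warning if they truncate the requested dimension.
#'
#' @param d A [pairwise_matrix()] of distances (symmetric, zero diagonal).
#' @param k Number of axes to return (default 10).
#' @return An object of class `wasp_mds`: list with `sample_ids`,
#'   `coordinates` (n x k matrix, columns `C1..Ck`), `eigenvalues`.
#' @export
classical_mds <- function(d, k = 10L) {
  m <- d$values
  if (anyNA(m)) stop("distance matrix contains undefined entries",
                     call. = FALSE)
  n <- nrow(m)
  k <- min(k, n - 1L)
  fit <- cmdscale(as.dist(m), k = k, eig = TRUE)
  pos <- sum(fit$eig > 1e-10)
  if (pos < k) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    pos, pos))
    k <- pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  # canonical sign: largest |loading| per axis is positive
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(d$labels, paste0("C", seq_len(ncol(coords))))
  structure(
    list(sample_ids = d$labels, coordinates = coords,
         eigenvalues = fit$eig[seq_len(k)]),
    class = "wasp_mds"
  )
}

#' @export
print.wasp_mds <- function(x, ...) {
  cat(sprintf("<mds> %d samples, %d axes\n",
              length(x$sample_ids), ncol(x$coordinates)))
  cat("  eigenvalues:", signif(head(x$eigenvalues, 5), 4),
      if (length(x$eigenvalues) > 5) "..." else "", "\n")
  invisible(x)
}

#' MDS coordinates as a tibble
#' @param x A `wasp_mds` from [classical_mds()].
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per axis.
#' @export
tidy.wasp_mds <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids),
                   tibble::as_tibble(x$coordinates))
}

#' Seeded balanced subsample of samples per group
#'
#' Utility for avoiding over-representation of densely sampled regions in
#' MDS or clustering: draws at most `n_per_group` sample ids per group,
#' reproducibly for a given seed.
#'
#' @param meta Sample metadata.
#' @param grouping Metadata column defining groups.
#' @param n_per_group Maximum samples retained per group.
#' @param seed Integer seed.
#' @return Character vector of retained sample ids.
#' @export
balanced_subsample <- function(meta, grouping = "region_label",
                               n_per_group = 8L, seed = 1L) {
  set.seed(seed)
  unlist(lapply(split(meta$sample_id, meta[[grouping]]), function(ids) {
    if (length(ids) <= n_per_group) ids else sort(sample(ids, n_per_group))
  }), use.names = FALSE)
}
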