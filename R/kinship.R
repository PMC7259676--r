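#' KING-robust pairwise kinship
#'
#' Within-pair kinship estimator robust to population structure, computed
#' from heterozygote and opposite-homozygote counts over the sites
#' non-missing in both samples:
#' \deqn{\phi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where \eqn{N_{Aa,Aa}} counts sites where both samples are heterozygous,
#' \eqn{N_{AA,aa}} counts opposite homozygotes, and \eqn{N_{Aa}(\cdot)} is
#' each sample's heterozygote count over the shared sites. A duplicated
#' (or self-compared) sample with at least one heterozygous site gives
#' \eqn{\phi = 0.5}; parent-offspring pairs expect about 0.25. Pairs with a
#' zero denominator are returned as `NA` (undefined).
#'
#' @param g A [genotype_matrix()] with at least 2 samples.
#' @return A `kinship_matrix`: list with `sample_ids`, `phi` (symmetric,
#'   diagonal 0.5 by convention), and `n_shared_sites`.
#' @export
king_kinship <- function(g) {
  if (n_samples(g) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- g$calls
  obs <- !is.na(x)
  het <- (!is.na(x) & x == 1L) * 1
  hom0 <- (!is.na(x) & x == 0L) * 1
  hom2 <- (!is.na(x) & x == 2L) * 1
  mode(obs) <- "numeric"

  n_het_both <- tcrossprod(het)                  # N_Aa,Aa
  n_opp <- tcrossprod(hom0, hom2)
  n_opp <- n_opp + t(n_opp)                      # N_AA,aa
  het_shared <- tcrossprod(het, obs)             # het in i over sites seen in j
  denom <- het_shared + t(het_shared)
  phi <- (n_het_both - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  diag(phi) <- 0.5
  n_shared <- tcrossprod(obs)
  dimnames(phi) <- dimnames(n_shared) <- list(g$sample_ids, g$sample_ids)
  structure(
    list(sample_ids = g$sample_ids, phi = phi, n_shared_sites = n_shared),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d samples\n", length(x$sample_ids)))
  off <- x$phi[upper.tri(x$phi)]
  cat(sprintf("  pairwise phi: median %.4f, max %.4f, %d undefined\n",
              stats::median(off, na.rm = TRUE), max(off, na.rm = TRUE),
              sum(is.na(off))))
  invisible(x)
}

#' Pairwise kinship as a tibble
#' @param x A `kinship_matrix` from [king_kinship()].
#' @param ... Unused.
#' @return Tibble with `sample_i`, `sample_j`, `phi`, `n_shared_sites`.
#' @export
tidy.kinship_matrix <- function(x, ...) {
  pr <- which(upper.tri(x$phi), arr.ind = TRUE)
  tibble::tibble(
    sample_i = x$sample_ids[pr[, 1]],
    sample_j = x$sample_ids[pr[, 2]],
    phi = x$phi[pr],
    n_shared_sites = x$n_shared_sites[pr]
  )
}

#' Remove one member of each close-kin pair
#'
#' Iterative greedy pruning: while any pair exceeds the kinship threshold,
#' take the pair with the largest \eqn{\phi} and drop the member with the
#' higher missing-genotype fraction (ties broken by removing the
#' lexicographically larger sample id). Undefined \eqn{\phi} (no shared
#' informative sites) is treated as unrelated but reported.
#'
#' @param k A `kinship_matrix` from [king_kinship()].
#' @param g The matching [genotype_matrix()].
#' @param threshold Kinship cutoff; pairs with `phi > threshold` are split
#'   (default 0.1, i.e. looser than second-degree relatives).
#' @return List with `genotypes` (pruned [genotype_matrix()]) and `removed`
#'   (tibble: `sample_id`, `partner`, `phi`, `reason`).
#' @export
prune_related <- function(k, g, threshold = 0.1) {
  stopifnot(threshold >= 0, identical(k$sample_ids, g$sample_ids))
  phi <- k$phi
  diag(phi) <- NA_real_
  miss_frac <- rowMeans(is.na(g$calls))
  names(miss_frac) <- g$sample_ids
  active <- setNames(rep(TRUE, length(k$sample_ids)), k$sample_ids)
  removed <- list()
  repeat {
    sub <- phi[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA_real_
    over <- which(!is.na(sub) & sub > threshold, arr.ind = TRUE)
    if (nrow(over) == 0L) break
    vals <- sub[over]
    ids_a <- rownames(sub)[over[, 1]]
    ids_b <- colnames(sub)[over[, 2]]
    ord <- order(-vals, pmin(ids_a, ids_b), pmax(ids_a, ids_b))[1]
    a <- ids_a[ord]; b <- ids_b[ord]; v <- vals[ord]
    drop_id <- if (miss_frac[a] > miss_frac[b]) a
      else if (miss_frac[b] > miss_frac[a]) b
      else max(a, b)
    keep_id <- setdiff(c(a, b), drop_id)
    active[drop_id] <- FALSE
    removed[[length(removed) + 1L]] <- tibble::tibble(
      sample_id = drop_id, partner = keep_id, phi = v,
      reason = sprintf("phi %.4f > %.4f; higher missingness or later id",
                       v, threshold)
    )
  }
  removed <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble::tibble(sample_id = character(), partner = character(),
                   phi = numeric(), reason = character())
  list(genotypes = subset_samples(g, names(active)[active]),
       removed = removed)
}
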