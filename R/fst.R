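#' Weir-Cockerham F_ST between two populations
#'
#' The weighted (ratio-of-sums) two-population Weir-Cockerham (1984)
#' estimator \eqn{\hat\theta = \sum_s a_s / \sum_s (a_s+b_s+c_s)}, where
#' `a`, `b`, `c` are the among-population, among-individual and
#' within-individual variance components computed per site from the sample
#' sizes, allele frequencies and observed heterozygote fractions over
#' non-missing calls. Sites with no calls in either population are skipped.
#' The estimate can be slightly negative in the absence of differentiation;
#' it is returned unclamped.
#'
#' @param g A [genotype_matrix()].
#' @param pop_a,pop_b Character vectors of sample ids (each of size >= 2,
#'   disjoint).
#' @return Numeric F_ST estimate.
#' @export
wc_fst <- function(g, pop_a, pop_b) {
  if (length(pop_a) < 2L || length(pop_b) < 2L) {
    stop("both populations need at least 2 samples", call. = FALSE)
  }
  ca <- subset_samples(g, pop_a)$calls
  cb <- subset_samples(g, pop_b)$calls
  sa <- site_freq_stats(ca)
  sb <- site_freq_stats(cb)
  comp <- wc_components(sa$n, sa$p, sa$ho, sb$n, sb$p, sb$ho)
  if (!any(comp$usable)) stop("no sites usable in both populations",
                              call. = FALSE)
  denom <- sum(comp$a[comp$usable] + comp$b[comp$usable] + comp$c[comp$usable])
  if (denom == 0) stop("no genetic variation at usable sites", call. = FALSE)
  sum(comp$a[comp$usable]) / denom
}

# vectorized per-site WC (1984) variance components, r = 2 populations
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- b[!usable] <- cc[!usable] <- 0
  list(a = a, b = b, c = cc, usable = usable)
}

#' Pairwise nuclear F_ST matrix over a grouping
#'
#' @param g A [genotype_matrix()].
#' @param meta Sample metadata (see [read_sample_table()]).
#' @param grouping Metadata column defining populations.
#' @param min_n Populations with fewer samples are dropped with a message.
#' @return A [pairwise_matrix()] (`statistic = "fst_nuclear"`), diagonal 0.
#' @export
fst_matrix <- function(g, meta, grouping = "region_label", min_n = 2L) {
  meta <- meta[match(g$sample_ids, meta$sample_id), ]
  groups <- split(meta$sample_id, meta[[grouping]])
  small <- names(groups)[lengths(groups) < min_n]
  if (length(small)) {
    message("dropping populations with < ", min_n, " samples: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= min_n]
  }
  labs <- names(groups)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- wc_fst(g, groups[[labs[i]]], groups[[labs[j]]])
  }
  pairwise_matrix(m, "fst_nuclear")
}

#' Mitochondrial diversity and Hudson F_ST from haplotype sequences
#'
#' Alignment columns containing any character outside \{A, C, G, T\} in any
#' retained sample are dropped globally first, for determinism. Within-
#' population diversity \eqn{\pi_{mt}} is the mean pairwise Hamming
#' difference per usable site. Pairwise differentiation is Hudson's
#' \eqn{F_{ST} = 1 - H_w / H_b}, where \eqn{H_w} averages the two
#' populations' mean within-population pairwise differences and \eqn{H_b}
#' is the mean between-population pairwise difference. Populations of one
#' sequence get `NA` \eqn{\pi_{mt}} and are excluded from the F_ST matrix.
#'
#' @param h A [haplotype_set()].
#' @param pops Named list of sample-id vectors (a partition of the samples
#'   to use).
#' @return List with `pi_mt` (named vector, per usable site), `fst`
#'   (a [pairwise_matrix()], `statistic = "fst_mito"`; `NA` where
#'   \eqn{H_b = 0}), and `n_usable_sites`.
#' @export
mito_pi_and_fst <- function(h, pops) {
  stopifnot(length(pops) >= 1, !is.null(names(pops)))
  ids <- unlist(pops, use.names = FALSE)
  if (anyDuplicated(ids)) stop("pops must be disjoint", call. = FALSE)
  missing_ids <- setdiff(ids, h$sample_ids)
  if (length(missing_ids)) {
    stop("samples without haplotypes: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  seqs <- h$sequences[ids]
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bad <- matrix(!(chars %in% c("A", "C", "G", "T")), nrow = nrow(chars))
  ok_col <- colSums(bad) == 0
  chars <- chars[, ok_col, drop = FALSE]
  L <- ncol(chars)
  if (L == 0L) stop("no unambiguous alignment columns", call. = FALSE)
  # Hamming distances via per-base match counts
  matches <- matrix(0, nrow(chars), nrow(chars))
  for (b in c("A", "C", "G", "T")) {
    ind <- (chars == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  dmat <- L - matches
  dimnames(dmat) <- list(ids, ids)

  within_mean <- function(members) {
    if (length(members) < 2L) return(NA_real_)
    sub <- dmat[members, members, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  pi_mt <- vapply(pops, function(m) within_mean(m) / L, numeric(1))

  usable_pops <- names(pops)[lengths(pops) >= 2L]
  m <- matrix(NA_real_, length(usable_pops), length(usable_pops),
              dimnames = list(usable_pops, usable_pops))
  diag(m) <- 0
  for (i in seq_along(usable_pops)) for (j in seq_len(i - 1L)) {
    pa <- pops[[usable_pops[i]]]; pb <- pops[[usable_pops[j]]]
    hw <- (within_mean(pa) + within_mean(pb)) / 2
    hb <- mean(dmat[pa, pb])
    m[i, j] <- m[j, i] <- if (hb == 0) NA_real_ else 1 - hw / hb
  }
  list(pi_mt = pi_mt, fst = pairwise_matrix(m, "fst_mito"),
       n_usable_sites = L)
}
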