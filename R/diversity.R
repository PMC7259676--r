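window_index <- function(sites, window_bp) {
  # half-open windows [1, 1+w), [1+w, 1+2w), ... per chromosome
  paste0(sites$chrom, ":", (sites$pos - 1L) %/% window_bp)
}

site_freq_stats <- function(calls) {
  n_called <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  het <- colSums(calls == 1L, na.rm = TRUE)
  list(n = n_called, p = p, ho = ifelse(n_called > 0, het / n_called,
                                        NA_real_))
}

#' Windowed nucleotide diversity
#'
#' Per tiled window of `window_bp` bases (half-open, anchored at position 1
#' on each chromosome), nucleotide diversity is
#' \deqn{\pi_w = \frac{1}{w}\sum_{s \in w} 2\hat p_s \hat q_s
#'   \frac{2n_s}{2n_s - 1}}
#' with \eqn{\hat p_s} the alt-allele frequency over non-missing calls and
#' \eqn{n_s} the non-missing diploid count — i.e. the unbiased mean pairwise
#' difference per base, with the full window span (not callable sites) as
#' denominator so values are comparable with whole-genome per-bp diversity.
#'
#' @param g A [genotype_matrix()].
#' @param window_bp Window width in bp (> 0).
#' @param pop Optional character vector of sample ids (defaults to all).
#' @return List with `windows` (tibble: `chrom`, `start`, `end`,
#'   `n_sites`, `pi`) and `mean_pi`, the mean over windows that contain at
#'   least one genotyped site.
#' @export
windowed_pi <- function(g, window_bp = 10000L, pop = NULL) {
  stopifnot(window_bp > 0)
  if (!is.null(pop)) g <- subset_samples(g, pop)
  if (n_samples(g) == 0L) stop("empty population", call. = FALSE)
  st <- site_freq_stats(g$calls)
  usable <- st$n >= 1
  contrib <- ifelse(usable & st$n > 0,
                    2 * st$p * (1 - st$p) * (2 * st$n) /
                      pmax(2 * st$n - 1, 1), 0)
  win <- window_index(g$sites, window_bp)
  agg <- tibble::tibble(win = win, contrib = contrib,
                        genotyped = as.integer(usable)) |>
    dplyr::group_by(.data$win) |>
    dplyr::summarise(pi = sum(.data$contrib) / window_bp,
                     n_sites = sum(.data$genotyped), .groups = "drop")
  parts <- strsplit(agg$win, ":", fixed = TRUE)
  wstart <- vapply(parts, function(x) as.integer(x[[2]]), integer(1)) *
    window_bp + 1L
  windows <- tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = wstart, end = wstart + as.integer(window_bp) - 1L,
    n_sites = agg$n_sites, pi = agg$pi
  ) |> dplyr::arrange(.data$chrom, .data$start)
  list(windows = windows,
       mean_pi = mean(windows$pi[windows$n_sites > 0]))
}

#' Windowed heterozygosity and inbreeding coefficient
#'
#' Per polymorphic site, expected heterozygosity \eqn{H_e = 2\hat p\hat q}
#' and observed heterozygote fraction \eqn{H_o}; each window's `He`/`Ho` is
#' the average over its polymorphic sites, and the population-level values
#' are window means. The inbreeding coefficient is aggregated as a ratio of
#' sums across windows,
#' \deqn{F_{IS} = 1 - \frac{\sum_w H_{o,w}}{\sum_w H_{e,w}},}
#' which is stable when some windows have tiny \eqn{H_e}. `Fis` is `NA`
#' (with a warning) when there are no polymorphic sites. Inside the ratio,
#' \eqn{H_e} carries the small-sample factor \eqn{2n_s/(2n_s-1)} so that
#' \eqn{F_{IS}} centers on zero under Hardy-Weinberg proportions; the
#' reported `He` column stays on the raw \eqn{2\hat p\hat q} scale.
#'
#' @inheritParams windowed_pi
#' @return List with `windows` (tibble: `chrom`, `start`, `n_poly_sites`,
#'   `He`, `Ho`), and scalars `He`, `Ho`, `Fis`.
#' @export
het_and_fis <- function(g, window_bp = 10000L, pop = NULL) {
  if (!is.null(pop)) g <- subset_samples(g, pop)
  if (n_samples(g) < 2L) stop("need at least 2 samples", call. = FALSE)
  st <- site_freq_stats(g$calls)
  poly <- !is.na(st$p) & st$p > 0 & st$p < 1
  if (!any(poly)) {
    warning("no polymorphic sites; Fis undefined")
    return(list(windows = tibble::tibble(), He = NA_real_, Ho = NA_real_,
                Fis = NA_real_))
  }
  he <- 2 * st$p * (1 - st$p)
  he_u <- he * 2 * st$n / pmax(2 * st$n - 1, 1)   # unbiased, for the ratio
  win <- window_index(g$sites, window_bp)
  agg <- tibble::tibble(win = win[poly], he = he[poly], he_u = he_u[poly],
                        ho = st$ho[poly]) |>
    dplyr::group_by(.data$win) |>
    dplyr::summarise(He = mean(.data$he), He_u = mean(.data$he_u),
                     Ho = mean(.data$ho),
                     n_poly_sites = dplyr::n(), .groups = "drop")
  parts <- strsplit(agg$win, ":", fixed = TRUE)
  windows <- tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = vapply(parts, function(x) as.integer(x[[2]]), integer(1)) *
      as.integer(window_bp) + 1L,
    n_poly_sites = agg$n_poly_sites, He = agg$He, He_u = agg$He_u,
    Ho = agg$Ho
  ) |> dplyr::arrange(.data$chrom, .data$start)
  list(windows = windows, He = mean(windows$He), Ho = mean(windows$Ho),
       Fis = 1 - sum(windows$Ho) / sum(windows$He_u))
}

#' Table-1-style population summary
#'
#' Convenience wrapper computing, for each population in a grouping, the
#' sample count, mean windowed nucleotide diversity, mitochondrial
#' diversity (if haplotypes are given), window-mean He and Ho, and F_IS.
#'
#' @param g A [genotype_matrix()].
#' @param meta Sample metadata tibble (see [read_sample_table()]).
#' @param grouping Metadata column defining populations (default
#'   `"region_label"`).
#' @param h Optional [haplotype_set()] for mitochondrial diversity.
#' @param window_bp Window width in bp.
#' @return Tibble with one row per population: `population`, `n`, `pi`,
#'   `pi_mt`, `He`, `Ho`, `Fis`.
#' @export
population_summary <- function(g, meta, grouping = "region_label",
                               h = NULL, window_bp = 10000L) {
  meta <- meta[match(g$sample_ids, meta$sample_id), ]
  groups <- split(meta$sample_id, meta[[grouping]])
  pi_mt <- setNames(rep(NA_real_, length(groups)), names(groups))
  if (!is.null(h)) {
    mito <- mito_pi_and_fst(h, purrr::map(groups, ~intersect(.x, h$sample_ids)))
    pi_mt <- mito$pi_mt[names(groups)]
  }
  purrr::imap(groups, function(ids, label) {
    pw <- windowed_pi(g, window_bp, pop = ids)
    hf <- suppressWarnings(het_and_fis(g, window_bp, pop = ids))
    tibble::tibble(population = label, n = length(ids), pi = pw$mean_pi,
                   pi_mt = pi_mt[[label]], He = hf$He, Ho = hf$Ho,
                   Fis = hf$Fis)
  }) |> dplyr::bind_rows()
}
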