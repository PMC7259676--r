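#' Genotype matrix of biallelic SNP dosages
#'
#' The central nuclear-genotype container: a samples-by-sites matrix of
#' alternate-allele dosages (0, 1, 2; `NA` for missing) together with the
#' per-site records (chromosome, 1-based position, ref and alt alleles).
#' Phase is ignored throughout because every downstream statistic is a
#' function of allele frequencies and heterozygote fractions only.
#'
#' @param calls Integer matrix, samples x sites, entries in \{0, 1, 2, NA\}.
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per site; `pos` strictly increasing within each `chrom`).
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `sites` (tibble) and `sample_ids`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   calls = rbind(a = c(0L, 1L), b = c(2L, NA)),
#'   sites = data.frame(chrom = "1", pos = c(100L, 200L),
#'                      ref = c("A", "C"), alt = c("G", "T")),
#'   sample_ids = c("a", "b")
#' )
#' n_sites(g)
genotype_matrix <- function(calls, sites, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- tibble::as_tibble(sites)
  stopifnot(
    nrow(calls) == length(sample_ids),
    ncol(calls) == nrow(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites))
  )
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("calls must be alt-allele dosages in {0, 1, 2} or NA", call. = FALSE)
  }
  if (nrow(sites) > 1L) {
    ok <- unlist(lapply(split(sites$pos, sites$chrom), function(p) {
      length(p) < 2L || all(diff(p) > 0)
    }), use.names = FALSE)
    if (!all(ok)) {
      stop("site positions must be strictly increasing within a chromosome",
           call. = FALSE)
    }
  }
  dimnames(calls) <- list(sample_ids, NULL)
  structure(
    list(calls = calls, sites = sites, sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d biallelic sites\n",
              n_samples(x), n_sites(x)))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Dimensions of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Integer scalar.
#' @export
n_samples <- function(g) length(g$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(g) nrow(g$sites)

#' Subset a genotype matrix by sample or by site
#'
#' @param g A [genotype_matrix()].
#' @param samples Character vector of sample ids, or logical/integer index
#'   over samples.
#' @param sites Logical or integer index over sites.
#' @return A [genotype_matrix()] with the requested rows/columns; sample and
#'   site order follows the index.
#' @export
subset_samples <- function(g, samples) {
  if (is.character(samples)) {
    idx <- match(samples, g$sample_ids)
    if (anyNA(idx)) {
      stop("unknown sample ids: ",
           paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- seq_along(g$sample_ids)[samples]
  }
  genotype_matrix(g$calls[idx, , drop = FALSE], g$sites, g$sample_ids[idx])
}

#' @rdname subset_samples
#' @export
subset_sites <- function(g, sites) {
  idx <- seq_len(n_sites(g))[sites]
  genotype_matrix(g$calls[, idx, drop = FALSE],
                  g$sites[idx, , drop = FALSE], g$sample_ids)
}

#' Set of aligned haploid haplotype sequences
#'
#' Container for per-sample mitochondrial sequences: equal-length aligned
#' strings over \{A, C, G, T, N, -\}, e.g. concatenated mitochondrial genes.
#' Optional gene boundaries record which segment of the concatenation each
#' gene occupies.
#'
#' @param sequences Named character vector (names = sample ids), all the
#'   same number of characters.
#' @param gene_boundaries Optional data frame with columns `gene`, `start`,
#'   `end` (1-based inclusive, in concatenated coordinates); segments must
#'   tile without overlap.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(sequences, gene_boundaries = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must be uniquely named by sample id", call. = FALSE)
  }
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("all haplotype sequences must be aligned to the same length",
         call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (!is.null(gene_boundaries)) {
    gene_boundaries <- tibble::as_tibble(gene_boundaries)
    stopifnot(all(c("gene", "start", "end") %in% names(gene_boundaries)))
    gb <- gene_boundaries[order(gene_boundaries$start), ]
    if (any(gb$end < gb$start) ||
        any(gb$start[-1] != gb$end[-nrow(gb)] + 1L)) {
      stop("gene segments must tile the concatenated sequence without gaps ",
           "or overlap", call. = FALSE)
    }
  }
  structure(
    list(sample_ids = names(sequences), sequences = sequences,
         length = len, gene_boundaries = gene_boundaries),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d aligned sequences of length %d bp\n",
              length(x$sequences), x$length))
  if (!is.null(x$gene_boundaries)) {
    cat(sprintf("  genes: %s\n", paste(x$gene_boundaries$gene, collapse = ", ")))
  }
  invisible(x)
}

#' Labelled symmetric pairwise matrix
#'
#' Thin wrapper around a symmetric numeric matrix (F_ST, genetic distance,
#' or geographic km) keeping the statistic's name with the values.
#'
#' @param values Symmetric numeric matrix with identical row/col names.
#' @param statistic Name of the statistic (e.g. `"fst_nuclear"`,
#'   `"fst_mito"`, `"geo_km"`, `"ibs"`).
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, statistic) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            identical(rownames(values), colnames(values)),
            !is.null(rownames(values)))
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("pairwise matrix must be symmetric", call. = FALSE)
  }
  structure(list(values = values, labels = rownames(values),
                 statistic = statistic),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %s over %d labels\n",
              x$statistic, length(x$labels)))
  print(round(x$values, 5))
  invisible(x)
}

#' Long-format view of a pairwise matrix
#'
#' @param x A [pairwise_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `label_a`, `label_b`,
#'   and a value column named after the statistic.
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  n <- length(x$labels)
  if (n < 2L) {
    return(tibble::tibble(label_a = character(), label_b = character(),
                          value = numeric()))
  }
  pr <- which(upper.tri(x$values), arr.ind = TRUE)
  out <- tibble::tibble(
    label_a = x$labels[pr[, 1]],
    label_b = x$labels[pr[, 2]],
    value = x$values[pr]
  )
  names(out)[3] <- x$statistic
  out
}

pairs_upper <- function(m) m$values[upper.tri(m$values)]
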