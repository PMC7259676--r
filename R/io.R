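#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (v4.x, plain or bgzipped) with `vcfR` and encodes the GT
#' field of every sample as an alt-allele dosage. Phase separators (`/` or
#' `|`) are ignored; `./.` and `.` become missing.
#'
#' @param path Path to the VCF file.
#' @param biallelic_only If `TRUE` (default) drop multiallelic records and
#'   records whose ref or alt allele is not a single base (indels, MNPs,
#'   spanning deletions).
#' @return A [genotype_matrix()] with samples in VCF column order.
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) {
    stop("VCF has no sample columns: ", path, call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  keep <- rep(TRUE, nrow(fix))
  if (biallelic_only) {
    snp <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
      nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
      fix[, "ALT"] != "." & fix[, "REF"] %in% c("A", "C", "G", "T") &
      fix[, "ALT"] %in% c("A", "C", "G", "T")
    keep <- keep & snp
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) {
    warning("no usable SNP records in ", path)
  }
  # "0/1", "0|1", "1/1", "./.", "."  ->  dosage
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0" = 0L, "1" = 1L)
  dosage[] <- lookup[clean]
  genotype_matrix(
    calls = t(dosage),
    sites = tibble::tibble(
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = as.character(fix[, "REF"]),
      alt = as.character(fix[, "ALT"])
    ),
    sample_ids = colnames(gt)
  )
}

#' Write a genotype matrix as an uncompressed VCF v4.2
#'
#' Emits a minimal single-FORMAT (`GT`) VCF with unphased diploid genotypes;
#' dosage 0/1/2 becomes `0/0`, `0/1`, `1/1` and missing becomes `./.`.
#' Round-trips bit-exactly through [read_vcf()].
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=waspibd",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")
  )
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(g), ncol = n_samples(g))
  calls <- t(g$calls)
  ok <- !is.na(calls)
  gt[ok] <- code[calls[ok] + 1L]
  body <- paste(
    g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt, ".", "PASS",
    ".", "GT",
    do.call(paste, c(as.data.frame(gt, stringsAsFactors = FALSE),
                     list(sep = "\t"))),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned haplotype sequences from FASTA
#'
#' @param path FASTA of equal-length aligned haploid sequences (one per
#'   sample, named by sample id), e.g. concatenated mitochondrial genes.
#' @param gene_map Optional TSV with columns `gene`, `start`, `end` giving
#'   each gene's 1-based inclusive span in the concatenated alignment.
#' @return A [haplotype_set()].
#' @export
read_haplotypes <- function(path, gene_map = NULL) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (length(unique(Biostrings::width(seqs))) != 1L) {
    stop("sequences in ", path, " are not aligned to equal length",
         call. = FALSE)
  }
  gb <- NULL
  if (!is.null(gene_map)) {
    gb <- readr::read_tsv(gene_map, col_types = readr::cols(
      gene = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer()
    ), progress = FALSE)
  }
  haplotype_set(setNames(as.character(seqs), names(seqs)),
                gene_boundaries = gb)
}

#' Write a haplotype set to FASTA
#' @param h A [haplotype_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(h, path) {
  x <- Biostrings::DNAStringSet(h$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read the per-sample metadata table
#'
#' Tab-separated, header required; `.` marks a missing optional field.
#' Expected columns: `sample_id`, `site_label`, `region_label`, `latitude`,
#' `longitude`, `year` and optional `building_label`, `region_radius_km`.
#'
#' @param path TSV file path.
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path) {
  meta <- readr::read_tsv(path, na = c(".", "", "NA"), progress = FALSE,
                          show_col_types = FALSE)
  req <- c("sample_id", "site_label", "region_label", "latitude",
           "longitude", "year")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("metadata is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  bad_lat <- !is.na(meta$latitude) & abs(meta$latitude) > 90
  bad_lon <- !is.na(meta$longitude) & abs(meta$longitude) > 180
  if (any(bad_lat) || any(bad_lon)) {
    stop("coordinates out of range for samples: ",
         paste(meta$sample_id[bad_lat | bad_lon], collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Write the per-sample metadata table
#' @param meta Tibble as returned by [read_sample_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(meta, path) {
  out <- meta
  out[] <- lapply(out, function(x) ifelse(is.na(x), ".", as.character(x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
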