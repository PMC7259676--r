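#' Configuration for the full analysis pipeline
#'
#' Collects file paths and every tunable parameter of the standard analysis:
#' site filters (minimum call fraction 0.8, minor-allele count 3), kinship
#' pruning threshold 0.1, 10-kb windows for diversity, 10-kb thinning for
#' MDS, and the breeder densities at which dispersal is reported.
#'
#' @param vcf,mito_fasta,meta_tsv Input file paths (the mito FASTA may be
#'   `NULL` to skip mitochondrial stages).
#' @param grouping Metadata column defining populations.
#' @param max_missing,mac Site filters (see [filter_sites()]).
#' @param kinship_threshold Pairs above this kinship lose one member.
#' @param window_bp Window width for diversity statistics.
#' @param thin_bp Thinning window before MDS.
#' @param densities Breeder densities (per km^2) for dispersal estimates.
#' @param mds_axes Number of MDS axes.
#' @param permutations Mantel permutations for the IBD regression.
#' @param seed Integer seed covering every random step.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, mito_fasta = NULL, meta_tsv,
                            grouping = "region_label",
                            max_missing = 0.8, mac = 3L,
                            kinship_threshold = 0.1,
                            window_bp = 10000L, thin_bp = 10000L,
                            densities = c(1080, 2500),
                            mds_axes = 10L, permutations = 999L,
                            seed = 1L, out_dir = NULL) {
  for (p in c(vcf, mito_fasta, meta_tsv)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  stopifnot(all(densities > 0))
  structure(
    list(vcf = vcf, mito_fasta = mito_fasta, meta_tsv = meta_tsv,
         grouping = grouping, max_missing = max_missing, mac = mac,
         kinship_threshold = kinship_threshold, window_bp = window_bp,
         thin_bp = thin_bp, densities = densities, mds_axes = mds_axes,
         permutations = permutations, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full multi-scale structure and dispersal analysis
#'
#' Executes, in order: read inputs, site filtering, kinship pruning,
#' per-population diversity summary, pairwise nuclear and mitochondrial
#' F_ST, geographic distances, isolation-by-distance regression, Rousset
#' dispersal estimates (one per configured density), the sex-biased
#' dispersal test, MDS on thinned identity-by-state distances, and the
#' mitochondrial haplotype network. Every random step is governed by
#' `config$seed`; re-running the same config gives bit-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with elements `summary`
#'   (Table-1-style tibble), `fst_nuclear`, `fst_mito`, `geo_km`
#'   (pairwise matrices), `ibd`, `ibd_mito`, `dispersal` (list of
#'   [rousset_sigma()] results), `sex_bias`, `mds`, `network`, `pruned`
#'   (removal report), and `manifest` (stage log with input hashes).
#'   With a non-null `out_dir`, TSV/JSON files are also written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(
    seed = config$seed,
    inputs = vapply(
      c(vcf = config$vcf, mito_fasta = config$mito_fasta %||% "",
        meta = config$meta_tsv),
      function(p) if (nzchar(p)) unname(tools::md5sum(p)) else "",
      character(1)),
    params = config[c("max_missing", "mac", "kinship_threshold",
                      "window_bp", "thin_bp", "densities", "grouping")]
  )
  set.seed(config$seed)

  g <- stage("read_vcf", read_vcf(config$vcf))
  meta <- stage("read_meta", read_sample_table(config$meta_tsv))
  h <- if (!is.null(config$mito_fasta)) {
    stage("read_haplotypes", read_haplotypes(config$mito_fasta))
  }

  g <- stage("filter_sites",
             filter_sites(g, config$max_missing, config$mac))
  kin <- stage("kinship", king_kinship(g))
  pruned <- stage("prune_related",
                  prune_related(kin, g, config$kinship_threshold))
  g <- pruned$genotypes
  meta_kept <- meta[meta$sample_id %in% g$sample_ids, ]

  groups <- split(meta_kept$sample_id, meta_kept[[config$grouping]])
  groups <- groups[lengths(groups) >= 2L]
  h_groups <- if (!is.null(h)) {
    purrr::map(groups, ~intersect(.x, h$sample_ids))
  }

  summary_tbl <- stage("population_summary",
                       population_summary(g, meta_kept, config$grouping,
                                          h = h, window_bp = config$window_bp))
  fst_nuc <- stage("fst_nuclear",
                   fst_matrix(g, meta_kept, config$grouping))
  geo <- stage("geo_distance",
               geo_distance_matrix(meta_kept, config$grouping))
  geo <- pairwise_matrix(geo$values[fst_nuc$labels, fst_nuc$labels], "geo_km")
  ibd <- stage("ibd_regression",
               ibd_regression(fst_nuc, geo, permutations = config$permutations,
                              seed = config$seed))
  dispersal <- stage("rousset_sigma", if (ibd$slope_b > 0) {
    lapply(setNames(config$densities, paste0("De_", config$densities)),
           function(de) rousset_sigma(ibd$slope_b, de))
  } else {
    warning("non-positive IBD slope; no dispersal estimate")
    list()
  })

  fst_mito <- ibd_mito <- sex_bias <- network <- NULL
  if (!is.null(h)) {
    mito <- stage("fst_mito", mito_pi_and_fst(h, h_groups))
    fst_mito <- mito$fst
    ibd_mito <- stage("ibd_mito", tryCatch(
      ibd_regression(fst_mito, pairwise_matrix(
        geo$values[fst_mito$labels, fst_mito$labels], "geo_km")),
      error = function(e) NULL))
    sex_bias <- stage("sex_bias", sex_bias_test(fst_nuc, fst_mito))
    network <- stage("haplotype_network",
                     build_haplotype_network(h, h_groups))
  }

  thin <- stage("thin_sites", thin_sites(g, config$thin_bp))
  mds <- stage("mds", classical_mds(ibs_distance(thin), k = config$mds_axes))

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res <- structure(
    list(summary = summary_tbl, fst_nuclear = fst_nuc, fst_mito = fst_mito,
         geo_km = geo, ibd = ibd, ibd_mito = ibd_mito,
         dispersal = dispersal, sex_bias = sex_bias, mds = mds,
         network = network, pruned = pruned$removed, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d populations; mean pairwise nuclear F_ST = %.4f\n",
              length(x$fst_nuclear$labels),
              mean(pairs_upper(x$fst_nuclear))))
  print(x$ibd)
  for (d in x$dispersal) print(d)
  if (!is.null(x$sex_bias)) print(x$sex_bias)
  invisible(x)
}

# TSV/JSON export of every result table
write_pipeline_result <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name),
                                          progress = FALSE)
  w(res$summary, "population_summary.tsv")
  w(tidy(res$fst_nuclear), "fst_nuclear_pairs.tsv")
  w(tidy(res$geo_km), "geo_km_pairs.tsv")
  w(tidy(res$ibd), "ibd_pairs.tsv")
  w(tidy(res$mds), "mds_coordinates.tsv")
  if (!is.null(res$fst_mito)) w(tidy(res$fst_mito), "fst_mito_pairs.tsv")
  if (!is.null(res$network)) {
    nd <- res$network$nodes
    nd$samples <- vapply(nd$samples, paste, character(1), collapse = ",")
    w(nd, "network_nodes.tsv")
    w(res$network$edges, "network_edges.tsv")
  }
  if (nrow(res$pruned)) w(res$pruned, "removed_samples.tsv")
  js <- list(
    ibd = glance(res$ibd),
    ibd_mito = if (!is.null(res$ibd_mito)) glance(res$ibd_mito),
    dispersal = lapply(res$dispersal, tidy),
    sex_bias = if (!is.null(res$sex_bias)) glance(res$sex_bias),
    manifest = res$manifest
  )
  jsonlite::write_json(js, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE, force = TRUE)
  invisible(dir)
}
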