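#' Configuration for the lattice stepping-stone simulator
#'
#' Defines a torus lattice of demes with constant breeder numbers,
#' sex-specific axial dispersal (discretized Gaussian kernels, truncated at
#' 4 SD and renormalized), biallelic nuclear SNPs under a two-allele
#' mutation model, and a maternally inherited mitochondrial sequence under
#' infinite-sites mutation. Setting `haplodiploid = TRUE` makes males
#' haploid (sons develop from unfertilized eggs and fathers transmit their
#' single allele).
#'
#' @param lattice Integer `c(rows, cols)` of demes (a ring when one
#'   dimension is 1; torus otherwise).
#' @param deme_breeders Breeders per deme (even; split equally female/male).
#'   With `deme_spacing_km` this sets the effective density
#'   `De = deme_breeders / deme_spacing_km^2` recorded in the truth record.
#' @param deme_spacing_km Distance between adjacent demes, km.
#' @param sigma_f_km,sigma_m_km Female and male axial dispersal SD, km.
#' @param n_nuclear_sites Number of unlinked biallelic nuclear sites.
#' @param mu_nuclear Per-site per-generation nuclear mutation rate (flips
#'   between the two alleles).
#' @param mito_length_bp Length of the mitochondrial sequence.
#' @param mu_mito Per-site per-generation mitochondrial mutation rate
#'   (infinite sites: every mutation hits a fresh position).
#' @param generations Total generations to run (> `burn_in`; the cohort is
#'   sampled from the final generation).
#' @param burn_in Generations before any output is considered meaningful;
#'   defaults to `10 * deme_breeders`.
#' @param haplodiploid Logical; haploid males when `TRUE`.
#' @param sample_plan Data frame with columns `deme` (1-based deme index),
#'   `n` (females sampled) and `label` (population label).
#' @param seed Integer; the simulation is deterministic given the seed.
#' @return A `simulation_config` list (validated).
#' @export
simulation_config <- function(lattice = c(1L, 20L),
                              deme_breeders = 30L,
                              deme_spacing_km = 3,
                              sigma_f_km = 1.5,
                              sigma_m_km = 1.5,
                              n_nuclear_sites = 300L,
                              mu_nuclear = 1e-5,
                              mito_length_bp = 1000L,
                              mu_mito = 5e-5,
                              generations = NULL,
                              burn_in = NULL,
                              haplodiploid = FALSE,
                              sample_plan = NULL,
                              seed = 1L) {
  if (is.null(burn_in)) burn_in <- 10L * deme_breeders
  if (is.null(generations)) generations <- burn_in + 2L
  stopifnot(length(lattice) == 2L, all(lattice >= 1L),
            deme_breeders >= 4L, deme_breeders %% 2L == 0L,
            deme_spacing_km > 0, sigma_f_km >= 0, sigma_m_km >= 0,
            n_nuclear_sites >= 1L, mu_nuclear > 0, mu_nuclear < 1,
            mito_length_bp >= 1L, mu_mito > 0, mu_mito < 1,
            generations > burn_in, burn_in >= 0L)
  for (s in c(sigma_f_km, sigma_m_km)) {
    for (dim_size in lattice[lattice > 1L]) {
      if (s / deme_spacing_km >= dim_size / 2) {
        stop("dispersal kernel SD (", s / deme_spacing_km,
             " demes) must be < lattice extent/2 (", dim_size / 2,
             ") to avoid boundary artifacts", call. = FALSE)
      }
    }
  }
  if (!is.null(sample_plan)) {
    sample_plan <- tibble::as_tibble(sample_plan)
    stopifnot(all(c("deme", "n", "label") %in% names(sample_plan)),
              all(sample_plan$deme >= 1L),
              all(sample_plan$deme <= prod(lattice)),
              all(sample_plan$n >= 1L),
              all(sample_plan$n <= deme_breeders %/% 2L))
    if (nrow(sample_plan) == 0L) stop("empty sample plan", call. = FALSE)
  }
  structure(
    list(lattice = as.integer(lattice), deme_breeders = as.integer(deme_breeders),
         deme_spacing_km = deme_spacing_km, sigma_f_km = sigma_f_km,
         sigma_m_km = sigma_m_km, n_nuclear_sites = as.integer(n_nuclear_sites),
         mu_nuclear = mu_nuclear, mito_length_bp = as.integer(mito_length_bp),
         mu_mito = mu_mito, generations = as.integer(generations),
         burn_in = as.integer(burn_in), haplodiploid = isTRUE(haplodiploid),
         sample_plan = sample_plan, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# discretized Gaussian over deme offsets: integrate the density over unit
# bins, truncate at 4 SD (and at half the ring so offsets are unambiguous),
# renormalize
dispersal_kernel <- function(sigma_km, spacing_km, size) {
  if (size == 1L || sigma_km == 0) {
    return(list(offsets = 0L, probs = 1, sd_demes = 0))
  }
  s <- sigma_km / spacing_km
  K <- max(1L, min(ceiling(4 * s), (size - 1L) %/% 2L))
  off <- (-K):K
  p <- pnorm(off + 0.5, 0, s) - pnorm(off - 0.5, 0, s)
  p <- p / sum(p)
  list(offsets = off, probs = p, sd_demes = sqrt(sum(p * off^2)))
}

#' Theoretical isolation-by-distance slope for a simulation configuration
#'
#' Inverts the Rousset relation: with effective density
#' `De = deme_breeders / spacing^2` and the realized (discretized,
#' truncated) kernel SDs, the predicted linearized-F_ST slope per km is
#' `b = 1/(4 pi De sigma^2)` with `sigma^2 = (sigma_f_eff^2 +
#' sigma_m_eff^2)/2` for nuclear (autosomal gene copies move through
#' mothers and fathers equally) and `sigma_f_eff^2` for the maternally
#' inherited mitochondrion.
#'
#' @param config A [simulation_config()].
#' @return List: `b_nuclear`, `b_mito` (per km), `sigma_f_eff_km`,
#'   `sigma_m_eff_km`, `sigma_nuc_eff_km`, `De`.
#' @export
expected_slope <- function(config) {
  dims <- config$lattice[config$lattice > 1L]
  eff <- function(sigma) {
    if (length(dims) == 0L) return(0)
    sds <- vapply(dims, function(sz) {
      dispersal_kernel(sigma, config$deme_spacing_km, sz)$sd_demes
    }, numeric(1))
    mean(sds) * config$deme_spacing_km   # axial SD, identical per dimension
  }
  sf <- eff(config$sigma_f_km)
  sm <- eff(config$sigma_m_km)
  s_nuc <- sqrt((sf^2 + sm^2) / 2)
  De <- config$deme_breeders / config$deme_spacing_km^2
  list(
    b_nuclear = if (s_nuc > 0) 1 / (4 * pi * De * s_nuc^2) else Inf,
    b_mito = if (sf > 0) 1 / (4 * pi * De * sf^2) else Inf,
    sigma_f_eff_km = sf, sigma_m_eff_km = sm, sigma_nuc_eff_km = s_nuc,
    De = De
  )
}

#' Run the forward-time stepping-stone simulation
#'
#' Non-overlapping generations, Wright-Fisher within demes: each offspring's
#' mother is drawn uniformly from a deme displaced by the female kernel
#' (torus wrap), its father from a deme displaced by the male kernel.
#' Nuclear sites start at intermediate frequencies (drawn uniform on
#' 0.05-0.95) and drift under symmetric two-allele mutation; the
#' mitochondrial genealogy is tracked exactly and converted to sequences
#' under infinite sites at the end. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()] with a non-null `sample_plan`.
#' @return A `simulated_cohort`: list with `genotypes`
#'   ([genotype_matrix()] of sampled females), `meta` (sample table),
#'   `haplotypes` ([haplotype_set()]), and `truth` (sigmas, `De`, expected
#'   slopes, seed, pedigree of the sampled generation, and the parental
#'   generation's female dosages for kinship validation).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$sample_plan)) {
    stop("config$sample_plan is required", call. = FALSE)
  }
  set.seed(config$seed)
  rows <- config$lattice[1]; cols <- config$lattice[2]
  n_demes <- rows * cols
  bf <- config$deme_breeders %/% 2L   # females per deme
  bm <- config$deme_breeders - bf     # males per deme
  S <- config$n_nuclear_sites
  nf <- n_demes * bf
  nm <- n_demes * bm
  deme_row <- rep(seq_len(rows), each = cols)
  deme_col <- rep(seq_len(cols), times = rows)

  kern_f_r <- dispersal_kernel(config$sigma_f_km, config$deme_spacing_km, rows)
  kern_f_c <- dispersal_kernel(config$sigma_f_km, config$deme_spacing_km, cols)
  kern_m_r <- dispersal_kernel(config$sigma_m_km, config$deme_spacing_km, rows)
  kern_m_c <- dispersal_kernel(config$sigma_m_km, config$deme_spacing_km, cols)

  # initial standing variation at intermediate frequencies
  p0 <- runif(S, 0.05, 0.95)
  draw_alleles <- function(n) {
    matrix(rbinom(n * S, 1L, rep(p0, each = n)), nrow = n, ncol = S)
  }
  FA <- draw_alleles(nf); FB <- draw_alleles(nf)
  MA <- draw_alleles(nm)
  MB <- if (!config$haplodiploid) draw_alleles(nm) else NULL

  # mitochondrial genealogy: node 1 = ancestral haplotype
  mito_parent <- 1L      # parent of node i (0 for root); grown as needed
  mito_parent[1] <- 0L
  f_mito <- rep(1L, nf)

  draw_deme <- function(offspring_deme, kr, kc) {
    n <- length(offspring_deme)
    dr <- kr$offsets[sample.int(length(kr$offsets), n, replace = TRUE,
                                prob = kr$probs)]
    dc <- kc$offsets[sample.int(length(kc$offsets), n, replace = TRUE,
                                prob = kc$probs)]
    r <- ((deme_row[offspring_deme] - 1L + dr) %% rows) + 1L
    cc <- ((deme_col[offspring_deme] - 1L + dc) %% cols) + 1L
    (r - 1L) * cols + cc
  }
  gamete <- function(A, B, parent_idx) {
    n <- length(parent_idx)
    mask <- matrix(runif(n * S) < 0.5, n, S)
    g <- A[parent_idx, , drop = FALSE]
    gb <- B[parent_idx, , drop = FALSE]
    g[mask] <- gb[mask]
    n_mut <- rbinom(1L, n * S, config$mu_nuclear)
    if (n_mut > 0L) {
      at <- sample.int(n * S, n_mut)
      g[at] <- 1L - g[at]
    }
    g
  }
  mutate_mito <- function(hap_ids) {
    k <- rpois(length(hap_ids), config$mu_mito * config$mito_length_bp)
    for (i in which(k > 0L)) {
      for (j in seq_len(k[i])) {
        mito_parent[length(mito_parent) + 1L] <<- hap_ids[i]
        hap_ids[i] <- length(mito_parent)
      }
    }
    hap_ids
  }

  od_f <- rep(seq_len(n_demes), each = bf)
  od_m <- rep(seq_len(n_demes), each = bm)
  pick_within <- function(demes, per_deme) {
    (demes - 1L) * per_deme + sample.int(per_deme, length(demes),
                                         replace = TRUE)
  }

  pedigree <- NULL
  for (gen in seq_len(config$generations)) {
    mother_f <- pick_within(draw_deme(od_f, kern_f_r, kern_f_c), bf)
    father_f <- pick_within(draw_deme(od_f, kern_m_r, kern_m_c), bm)
    new_FA <- gamete(FA, FB, mother_f)
    new_FB <- if (config$haplodiploid) {
      gamete(MA, MA, father_f)          # haploid father: single allele
    } else {
      gamete(MA, MB, father_f)
    }
    new_f_mito <- mutate_mito(f_mito[mother_f])

    mother_m <- pick_within(draw_deme(od_m, kern_f_r, kern_f_c), bf)
    new_MA <- gamete(FA, FB, mother_m)
    if (config$haplodiploid) {
      new_MB <- NULL; father_m <- rep(NA_integer_, nm)
    } else {
      father_m <- pick_within(draw_deme(od_m, kern_m_r, kern_m_c), bm)
      new_MB <- gamete(MA, MB, father_m)
    }

    if (gen == config$generations) {
      pedigree <- list(mother_f = mother_f, father_f = father_f,
                       parent_female_dosage = FA + FB)
    }
    FA <- new_FA; FB <- new_FB; MA <- new_MA; MB <- new_MB
    f_mito <- new_f_mito
  }

  # --- sample females per plan -------------------------------------------
  plan <- config$sample_plan
  picks <- integer(0)
  labels <- character(0)
  for (i in seq_len(nrow(plan))) {
    block <- ((plan$deme[i] - 1L) * bf + 1L):(plan$deme[i] * bf)
    picks <- c(picks, sort(sample(block, plan$n[i])))
    labels <- c(labels, rep(plan$label[i], plan$n[i]))
  }
  sample_ids <- sprintf("S%03d", seq_along(picks))

  dosage <- FA[picks, , drop = FALSE] + FB[picks, , drop = FALSE]
  positions <- sort(sample.int(S * 10000L, S))
  g <- genotype_matrix(
    dosage,
    tibble::tibble(chrom = "chr1", pos = positions,
                   ref = "A", alt = "G"),
    sample_ids
  )

  deme_of <- plan$deme[rep(seq_len(nrow(plan)), plan$n)]
  x_km <- (deme_col[deme_of] - 1L) * config$deme_spacing_km
  y_km <- (deme_row[deme_of] - 1L) * config$deme_spacing_km
  meta <- tibble::tibble(
    sample_id = sample_ids,
    site_label = sprintf("deme_%02d", deme_of),
    region_label = labels,
    latitude = 42 + y_km / 111.32,
    longitude = -76 + x_km / (111.32 * cos(42 * pi / 180)),
    year = 2015L,
    building_label = NA_character_
  )

  seqs <- mito_sequences(f_mito[picks], mito_parent,
                         config$mito_length_bp)
  names(seqs) <- sample_ids
  h <- haplotype_set(seqs)

  es <- expected_slope(config)
  truth <- list(
    sigma_f_km = config$sigma_f_km, sigma_m_km = config$sigma_m_km,
    sigma_f_eff_km = es$sigma_f_eff_km, sigma_m_eff_km = es$sigma_m_eff_km,
    sigma_nuc_eff_km = es$sigma_nuc_eff_km,
    De = es$De, b_nuclear_expected = es$b_nuclear,
    b_mito_expected = es$b_mito, seed = config$seed,
    haplodiploid = config$haplodiploid,
    pedigree = tibble::tibble(
      sample_id = sample_ids,
      mother_index = pedigree$mother_f[picks],
      father_index = pedigree$father_f[picks]
    ),
    parent_female_dosage = pedigree$parent_female_dosage
  )
  structure(list(genotypes = g, meta = meta, haplotypes = h, truth = truth,
                 config = config),
            class = "simulated_cohort")
}

# convert tracked mitochondrial genealogy nodes to concrete sequences:
# each mutation node on an ancestry path of a sampled haplotype gets a
# fresh position (infinite sites) and a base different from the ancestral
# one; mutations on extinct lineages never materialize
mito_sequences <- function(hap_ids, mito_parent, L) {
  n_nodes <- length(mito_parent)
  needed <- logical(n_nodes)
  for (id in unique(hap_ids)) {
    node <- id
    while (node != 0L && !needed[node]) {
      needed[node] <- TRUE
      node <- mito_parent[node]
    }
  }
  mut_nodes <- setdiff(which(needed), 1L)
  if (length(mut_nodes) > L) {
    stop("more segregating mitochondrial mutations than sites; ",
         "increase mito_length_bp or lower mu_mito", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  mut_pos <- setNames(sample.int(L, length(mut_nodes)),
                      as.character(mut_nodes))
  mut_base <- vapply(as.character(mut_nodes), function(k) {
    sample(setdiff(bases, root[mut_pos[k]]), 1L)
  }, character(1))
  cache <- new.env(parent = emptyenv())
  node_seq <- function(node) {
    key <- as.character(node)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- if (mito_parent[node] == 0L) root else node_seq(mito_parent[node])
    if (node > 1L) s[mut_pos[[key]]] <- mut_base[[key]]
    cache[[key]] <- s
    s
  }
  vapply(hap_ids, function(id) paste(node_seq(id), collapse = ""),
         character(1))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "<simulated_cohort> %d sampled females, %d nuclear sites, seed %d\n",
    n_samples(x$genotypes), n_sites(x$genotypes), x$truth$seed))
  cat(sprintf("  truth: sigma_f = %.3f km (eff %.3f), sigma_m = %.3f km, De = %.3g /km^2\n",
              x$truth$sigma_f_km, x$truth$sigma_f_eff_km,
              x$truth$sigma_m_km, x$truth$De))
  invisible(x)
}

#' Write a simulated cohort to standard file formats
#'
#' Emits `nuclear.vcf` (uncompressed VCF v4.2), `mito.fasta`,
#' `samples.tsv` and `truth.json` into `dir`. Re-reading the VCF and FASTA
#' reproduces the in-memory cohort bit-exactly.
#'
#' @param cohort A `simulated_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "nuclear.vcf"),
    fasta = file.path(dir, "mito.fasta"),
    meta = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(cohort$genotypes, paths["vcf"])
  write_haplotypes(cohort$haplotypes, paths["fasta"])
  write_sample_table(cohort$meta, paths["meta"])
  truth <- cohort$truth
  truth$parent_female_dosage <- NULL   # bulky; kept in memory only
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Evenly spaced transect sampling plan along the ring dimension
#'
#' Confines sampling to a contiguous arc of at most half the ring, so that
#' straight-line distances between sampled demes equal distances on the
#' torus.
#'
#' @param config A [simulation_config()] (ring lattice: one dimension = 1).
#' @param n_demes Number of demes to sample along the arc.
#' @param n_per_deme Females sampled per deme.
#' @return A sampling-plan tibble for [simulation_config()].
#' @export
transect_sample_plan <- function(config, n_demes = 8L, n_per_deme = 12L) {
  len <- max(config$lattice)
  stopifnot(min(config$lattice) == 1L, n_demes >= 2L,
            n_demes <= len %/% 2L + 1L)
  tibble::tibble(
    deme = as.integer(round(seq(1L, len %/% 2L + 1L, length.out = n_demes))),
    n = as.integer(n_per_deme),
    label = sprintf("pop_%02d", seq_len(n_demes))
  )
}
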