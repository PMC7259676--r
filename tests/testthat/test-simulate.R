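small_plan <- tibble::tibble(deme = c(1L, 3L), n = 6L,
                             label = c("west", "east"))
small_cfg <- function(seed = 1L, ...) {
  args <- list(lattice = c(1L, 6L), deme_breeders = 16L,
               n_nuclear_sites = 120L, generations = 60L, burn_in = 50L,
               sample_plan = small_plan, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

test_that("configuration validation rejects degenerate setups", {
  expect_error(small_cfg(sigma_f_km = 100),
               "lattice extent")                     # kernel too wide
  expect_error(small_cfg(sample_plan = tibble::tibble(
    deme = 1L, n = 50L, label = "x")))               # n > females per deme
  expect_error(small_cfg(generations = 10L, burn_in = 50L))
  expect_error(simulate_cohort(small_cfg(sample_plan = NULL)),
               "sample_plan")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(small_cfg(seed = 5L))
  b <- simulate_cohort(small_cfg(seed = 5L))
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$haplotypes$sequences, b$haplotypes$sequences)
  expect_identical(a$meta, b$meta)
  c2 <- simulate_cohort(small_cfg(seed = 6L))
  expect_false(identical(a$genotypes$calls, c2$genotypes$calls))
})

test_that("written cohorts round-trip and are byte-identical across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co <- simulate_cohort(small_cfg(seed = 8L))
  p1 <- write_cohort(co, d1)
  p2 <- write_cohort(simulate_cohort(small_cfg(seed = 8L)), d2)
  for (f in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))
  }
  g <- read_vcf(p1[["vcf"]])
  expect_identical(g$calls, co$genotypes$calls)
  expect_identical(g$sites$pos, co$genotypes$sites$pos)
  h <- read_haplotypes(p1[["fasta"]])
  expect_identical(h$sequences, co$haplotypes$sequences)
  meta <- read_sample_table(p1[["meta"]])
  expect_identical(meta$sample_id, co$meta$sample_id)
  expect_equal(meta$latitude, co$meta$latitude, tolerance = 1e-9)
  truth <- jsonlite::read_json(p1[["truth"]])
  expect_equal(truth$De, co$truth$De)
})

test_that("synthesized coordinates reproduce lattice distances", {
  co <- simulate_cohort(small_cfg(seed = 9L))
  d <- geo_distance_matrix(co$meta, "region_label")
  # demes 1 and 3 on a 3-km lattice: 6 km apart
  expect_equal(d$values["west", "east"], 6, tolerance = 0.005 * 6)
})

test_that("per-generation drift variance scales as p(1-p)/(2N)", {
  # isolated demes (sigma = 0): compare allele-frequency steps between a
  # G-generation and a (G+1)-generation run of the same seed; sampling all
  # females censuses the female pool exactly
  plan <- tibble::tibble(deme = c(1L, 2L), n = 10L, label = c("a", "b"))
  base <- list(lattice = c(1L, 2L), deme_breeders = 20L, sigma_f_km = 0,
               sigma_m_km = 0, n_nuclear_sites = 500L, mu_nuclear = 1e-9,
               burn_in = 10L, sample_plan = plan)
  z2 <- c()
  for (seed in 1:3) {
    g1 <- simulate_cohort(do.call(simulation_config,
                                  c(base, generations = 40L, seed = seed)))
    g2 <- simulate_cohort(do.call(simulation_config,
                                  c(base, generations = 41L, seed = seed)))
    for (lab in c("a", "b")) {
      ids <- g1$meta$sample_id[g1$meta$region_label == lab]
      p1 <- colMeans(g1$genotypes$calls[ids, ]) / 2
      p2 <- colMeans(g2$genotypes$calls[ids, ]) / 2
      keep <- p1 > 0.15 & p1 < 0.85
      # censusing only the B_f = 10 females: the new female-pool frequency
      # is the mean of two parental-pool means (var pq/20 given the
      # parental pools) plus the stationary female-male pool offset
      # (E[((p_M-p_F)/2)^2] = pq/40), so E[(step)^2] = 3 pq/40 -- the
      # whole-deme drift variance pq/(2N) seen through the female census
      z2 <- c(z2, ((p2 - p1)^2 / (p1 * (1 - p1)))[keep] * 40 / 3)
    }
  }
  expect_gt(mean(z2), 0.8)
  expect_lt(mean(z2), 1.25)
})

test_that("mitochondrial diversity falls below nuclear at equal mutation rate", {
  plan <- tibble::tibble(deme = 1L, n = 10L, label = "pop")
  ratio <- vapply(1:4, function(seed) {
    cfg <- simulation_config(lattice = c(1L, 1L), deme_breeders = 20L,
                             n_nuclear_sites = 200L, mu_nuclear = 1e-3,
                             mito_length_bp = 2000L, mu_mito = 1e-3,
                             generations = 200L, burn_in = 150L,
                             sample_plan = plan, seed = 500L + seed)
    co <- simulate_cohort(cfg)
    pw <- windowed_pi(co$genotypes, 10000L)
    nuc <- sum(pw$windows$pi) * 10000 / n_sites(co$genotypes)
    mito <- mito_pi_and_fst(co$haplotypes, list(pop = co$meta$sample_id))
    unname(mito$pi_mt["pop"]) / nuc
  }, numeric(1))
  expect_lt(mean(ratio), 1)   # maternal haploid Ne is a quarter of nuclear
})

test_that("expected slopes follow the Rousset relation and its monotonicity", {
  cfg <- small_cfg()
  es <- expected_slope(cfg)
  expect_equal(es$b_nuclear,
               1 / (4 * pi * es$De * es$sigma_nuc_eff_km^2),
               tolerance = 1e-12)
  expect_equal(es$b_mito, 1 / (4 * pi * es$De * es$sigma_f_eff_km^2),
               tolerance = 1e-12)
  expect_equal(es$De, 16 / 9, tolerance = 1e-12)

  cfg2 <- small_cfg(sigma_m_km = 3)
  es2 <- expected_slope(cfg2)
  expect_lt(es2$b_nuclear, es$b_nuclear)   # faster males flatten the slope
  expect_gte(es2$b_mito, es2$b_nuclear)    # mito slope >= nuclear slope
})

test_that("isolated demes diverge toward fixation with disjoint haplotypes", {
  plan <- tibble::tibble(deme = c(1L, 2L), n = 8L, label = c("a", "b"))
  cfg <- simulation_config(lattice = c(1L, 2L), deme_breeders = 16L,
                           sigma_f_km = 0, sigma_m_km = 0,
                           n_nuclear_sites = 200L, mu_mito = 2e-4,
                           generations = 400L, burn_in = 350L,
                           sample_plan = plan, seed = 77L)
  co <- simulate_cohort(cfg)
  fst <- wc_fst(co$genotypes, co$meta$sample_id[co$meta$region_label == "a"],
                co$meta$sample_id[co$meta$region_label == "b"])
  expect_gt(fst, 0.5)
  seq_a <- unique(co$haplotypes$sequences[co$meta$region_label == "a"])
  seq_b <- unique(co$haplotypes$sequences[co$meta$region_label == "b"])
  expect_length(intersect(seq_a, seq_b), 0)
})
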