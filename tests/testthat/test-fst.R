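test_that("undifferentiated and fully fixed populations bracket F_ST", {
  set.seed(2)
  p <- runif(60, 0.2, 0.8)
  hwe <- function(n) matrix(rbinom(n * 60, 2L, rep(p, each = n)), n)
  g <- genotype_matrix(rbind(hwe(15), hwe(15)),
                       tibble::tibble(chrom = "chr1", pos = 1:60 * 50L,
                                      ref = "A", alt = "G"),
                       sprintf("s%02d", 1:30))
  same <- wc_fst(g, sprintf("s%02d", 1:15), sprintf("s%02d", 16:30))
  expect_lt(abs(same), 0.05)   # near zero, may be slightly negative

  fixed <- genotype_matrix(
    rbind(matrix(0L, 4, 20), matrix(2L, 4, 20)),
    tibble::tibble(chrom = "chr1", pos = 1:20 * 50L, ref = "A", alt = "G"),
    sprintf("s%02d", 1:8))
  expect_equal(wc_fst(fixed, sprintf("s%02d", 1:4), sprintf("s%02d", 5:8)),
               1)
})

test_that("the documented 1-site toy matches the brute-force components", {
  # popA: n=4, p=0.75, Ho=0.5 (dosages 2,2,1,1); popB mirrored
  g <- genotype_matrix(
    matrix(c(2L, 2L, 1L, 1L, 0L, 0L, 1L, 1L), ncol = 1),
    tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G"),
    c(paste0("a", 1:4), paste0("b", 1:4)))
  impl <- wc_fst(g, paste0("a", 1:4), paste0("b", 1:4))
  oracle <- wc_fst_oracle(g, paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(impl, oracle, tolerance = 1e-12)
})

test_that("Weir-Cockerham agrees with the brute-force oracle on random data", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:10, 1)
    s <- sample(5:20, 1)
    g <- random_genotype_matrix(n, s, miss_rate = runif(1, 0, 0.3),
                                seed = seed + 1000)
    na <- if (n == 4L) 2L else sample(2:(n - 2), 1)
    pa <- g$sample_ids[1:na]
    pb <- g$sample_ids[(na + 1):n]
    impl <- tryCatch(wc_fst(g, pa, pb), error = function(e) NA_real_)
    if (is.na(impl)) next
    expect_equal(impl, wc_fst_oracle(g, pa, pb), tolerance = 1e-10)
  }
})

test_that("F_ST is symmetric and invariant to allele flips and site order", {
  g <- random_genotype_matrix(12, 50, miss_rate = 0.1, seed = 123)
  pa <- g$sample_ids[1:6]; pb <- g$sample_ids[7:12]
  base <- wc_fst(g, pa, pb)
  expect_equal(wc_fst(g, pb, pa), base, tolerance = 1e-14)

  flip <- g$calls
  flip[, 1:25] <- 2L - flip[, 1:25]
  g_flip <- genotype_matrix(flip, g$sites, g$sample_ids)
  expect_equal(wc_fst(g_flip, pa, pb), base, tolerance = 1e-12)

  perm <- sample(50)
  g_perm <- genotype_matrix(g$calls[, perm],
                            tibble::tibble(chrom = "chr1",
                                           pos = seq_len(50) * 10L,
                                           ref = "A", alt = "G"),
                            g$sample_ids)
  expect_equal(wc_fst(g_perm, pa, pb), base, tolerance = 1e-12)
})

test_that("island-model simulations match the exact identity recursion", {
  d <- 8; N <- 50; m <- 0.05; mu <- 1e-3
  expected <- island_fst_theory(d, N, m, mu)
  reps <- vapply(1:8, function(seed) {
    demes <- island_sim(d, N, m, mu, n_sites = 150, T_gen = 800,
                        n_sample = 12, seed = 300 + seed)
    calls <- do.call(rbind, demes[1:2])
    g <- genotype_matrix(calls,
                         tibble::tibble(chrom = "chr1",
                                        pos = seq_len(ncol(calls)) * 10L,
                                        ref = "A", alt = "G"),
                         sprintf("s%02d", seq_len(nrow(calls))))
    wc_fst(g, g$sample_ids[1:12], g$sample_ids[13:24])
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se)
})

test_that("mitochondrial diversity and Hudson F_ST behave on boundary cases", {
  same <- haplotype_set(setNames(rep("ACGTACGT", 6),
                                 sprintf("m%d", 1:6)))
  res <- mito_pi_and_fst(same, list(x = sprintf("m%d", 1:3),
                                    y = sprintf("m%d", 4:6)))
  expect_equal(unname(res$pi_mt), c(0, 0))
  expect_true(is.na(res$fst$values["x", "y"]))  # H_b = 0: undefined

  seqs <- c(rep("AAAAAAAAAA", 3), rep("CCCCCAAAAA", 3))  # 5 steps apart
  names(seqs) <- sprintf("m%d", 1:6)
  h <- haplotype_set(seqs)
  res2 <- mito_pi_and_fst(h, list(x = sprintf("m%d", 1:3),
                                  y = sprintf("m%d", 4:6)))
  expect_equal(res2$fst$values["x", "y"], 1)
})

test_that("Hudson F_ST equals exhaustive pair enumeration on toy sets", {
  seqs <- c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAA", a3 = "ACGTACGTCC",
            b1 = "TCGTACGTAC", b2 = "TCGAACGTAC", b3 = "TCGAACTTAC")
  h <- haplotype_set(seqs)
  res <- mito_pi_and_fst(h, list(a = c("a1", "a2", "a3"),
                                 b = c("b1", "b2", "b3")))
  oracle <- hudson_fst_oracle(seqs[1:3], seqs[4:6])
  expect_equal(res$fst$values["a", "b"], oracle, tolerance = 1e-12)

  # and on random sequence sets of up to 8 sequences
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    len <- 30
    mat <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1)), n, len)
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- sprintf("r%d", seq_len(n))
    na <- if (n == 4L) 2L else sample(2:(n - 2), 1)
    h <- haplotype_set(seqs)
    res <- mito_pi_and_fst(h, list(a = names(seqs)[1:na],
                                   b = names(seqs)[(na + 1):n]))
    expect_equal(res$fst$values["a", "b"],
                 hudson_fst_oracle(seqs[1:na], seqs[(na + 1):n]),
                 tolerance = 1e-12)
  }
})

test_that("columns with ambiguity characters are excluded globally", {
  seqs <- c(a1 = "ACGTN", a2 = "ACGTA", b1 = "TCGT-", b2 = "TCGTA")
  h <- haplotype_set(seqs)
  res <- mito_pi_and_fst(h, list(a = c("a1", "a2"), b = c("b1", "b2")))
  expect_identical(res$n_usable_sites, 4L)
})
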