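# Independent oracles and fixture builders used across the test files.
# Every oracle is deliberately written as a plain per-site / per-pair loop,
# separate from the vectorized implementations in the package.

random_genotype_matrix <- function(n, s, miss_rate = 0, seed = 1) {
  set.seed(seed)
  p <- runif(s, 0.05, 0.95)
  calls <- matrix(rbinom(n * s, 2L, rep(p, each = n)), nrow = n)
  if (miss_rate > 0) calls[runif(n * s) < miss_rate] <- NA_integer_
  genotype_matrix(
    calls,
    tibble::tibble(chrom = "chr1", pos = seq_len(s) * 100L,
                   ref = "A", alt = "G"),
    sprintf("ind%03d", seq_len(n))
  )
}

# Weir & Cockerham (1984) two-population theta, scalar loop over sites,
# following the published variance components with r = 2
wc_fst_oracle <- function(g, pop_a, pop_b) {
  ga <- subset_samples(g, pop_a)$calls
  gb <- subset_samples(g, pop_b)$calls
  r <- 2
  num <- den <- 0
  for (s in seq_len(ncol(ga))) {
    xa <- ga[, s][!is.na(ga[, s])]
    xb <- gb[, s][!is.na(gb[, s])]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    p1 <- sum(xa) / (2 * n1); p2 <- sum(xb) / (2 * n2)
    h1 <- mean(xa == 1); h2 <- mean(xb == 1)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Hudson F_ST by exhaustive enumeration of all sequence pairs
hudson_fst_oracle <- function(seqs_a, seqs_b) {
  ham <- function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  within_mean <- function(ss) {
    prs <- combn(length(ss), 2)
    mean(apply(prs, 2, function(ij) ham(ss[ij[1]], ss[ij[2]])))
  }
  hw <- (within_mean(seqs_a) + within_mean(seqs_b)) / 2
  hb <- mean(outer(seq_along(seqs_a), seq_along(seqs_b),
                   Vectorize(function(i, j) ham(seqs_a[i], seqs_b[j]))))
  1 - hw / hb
}

# minimum spanning-tree weight by exhaustive enumeration over all
# (n-1)-edge subsets (feasible for n <= 6)
mst_weight_oracle <- function(dmat) {
  n <- nrow(dmat)
  if (n == 1) return(0)
  prs <- t(combn(n, 2))
  w <- dmat[prs]
  best <- Inf
  for (sub in combn(nrow(prs), n - 1, simplify = FALSE)) {
    # connectivity check via repeated merging
    comp <- seq_len(n)
    for (e in sub) {
      ca <- comp[prs[e, 1]]; cb <- comp[prs[e, 2]]
      comp[comp == cb] <- ca
    }
    if (length(unique(comp)) == 1) best <- min(best, sum(w[sub]))
  }
  best
}

# haversine on a sphere, independent closed form
haversine_oracle <- function(lat1, lon1, lat2, lon2, r_km = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r_km * asin(sqrt(a))
}

# stationary distribution of the biallelic Wright-Fisher chain with
# symmetric two-allele mutation: C haploid copies, exact transition matrix
wf_stationary_pairdiff <- function(C, mu, tol = 1e-13) {
  p_next <- function(p) p * (1 - mu) + (1 - p) * mu
  Tm <- outer(0:C, 0:C, function(j, k) dbinom(k, C, p_next(j / C)))
  v <- rep(1 / (C + 1), C + 1)
  repeat {
    v2 <- as.vector(v %*% Tm)
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  k <- 0:C
  sum(v2 * 2 * k * (C - k) / (C * (C - 1)))   # P(two distinct copies differ)
}

# finite island model: exact second-moment recursion for the scheme used
# in island_sim (deterministic frequency mixing with the grand mean, then
# symmetric mutation, then binomial resampling of 2N copies per deme).
# Tracks beta = E[p_i^2] and gamma = E[p_i p_j] (i != j); E[p] = 1/2
# throughout by symmetry. F compares demes via probabilities that two
# distinct copies differ within (Hw) and between (Hb) demes.
island_fst_theory <- function(d, N, m, mu) {
  a <- 1 - m + m / d
  cc <- m / d
  k <- 1 - 2 * mu
  beta <- 0.25; gamma <- 0.25   # start at the deterministic p = 1/2 state
  for (it in 1:200000) {
    e_pm2 <- a^2 * beta + 2 * a * cc * (d - 1) * gamma +
      cc^2 * ((d - 1) * beta + (d - 1) * (d - 2) * gamma)
    e_pmij <- a^2 * gamma +
      2 * a * cc * (beta + (d - 2) * gamma) +
      cc^2 * ((d - 2) * beta + ((d - 1)^2 - (d - 2)) * gamma)
    # mutation: p* = mu + (1-2mu) pm
    e_s2 <- mu^2 + mu * k + k^2 * e_pm2
    e_sij <- mu^2 + mu * k + k^2 * e_pmij
    beta_new <- e_s2 + (0.5 - e_s2) / (2 * N)
    gamma_new <- e_sij
    if (abs(beta_new - beta) < 1e-15 && abs(gamma_new - gamma) < 1e-15) {
      beta <- beta_new; gamma <- gamma_new
      break
    }
    beta <- beta_new; gamma <- gamma_new
  }
  # island_sim draws sampled alleles iid Bern(p_i) (infinite-pool HWE), so
  # within-deme identity carries no finite-copy 2N/(2N-1) correction
  hw <- 2 * (0.5 - beta)
  hb <- 2 * (0.5 - gamma)
  1 - hw / hb
}

# allele-frequency-level island-model simulation matching the recursion
# above: d demes of 2N copies, migrant pool = grand mean, symmetric
# mutation; returns sampled HWE genotypes per deme after T generations
island_sim <- function(d, N, m, mu, n_sites, T_gen, n_sample, seed) {
  set.seed(seed)
  p <- matrix(0.5, d, n_sites)
  for (t in seq_len(T_gen)) {
    pool <- colMeans(p)
    pm <- (1 - m) * p + m * rep(pool, each = d)
    pm <- pm * (1 - mu) + (1 - pm) * mu
    p <- matrix(rbinom(d * n_sites, 2 * N, pm), d, n_sites) / (2 * N)
  }
  lapply(seq_len(d), function(i) {
    matrix(rbinom(n_sample * n_sites, 2L, rep(p[i, ], each = n_sample)),
           nrow = n_sample)
  })
}

# least-squares Procrustes superimposition (rotation + scale + translation)
procrustes_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(Yc^2)
  sqrt(mean((Xc - s * Yc %*% R)^2))
}

# per-site unbiased pairwise difference (for SEs across independent sites)
site_freq_stats_for_test <- function(g) {
  apply(g$calls, 2, function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    p <- sum(x) / (2 * n)
    2 * p * (1 - p) * 2 * n / (2 * n - 1)
  })
}

# tiny aligned FASTA writer for fixtures
write_fasta_fixture <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
}

simple_meta <- function(ids, region, lat, lon, site = region) {
  tibble::tibble(sample_id = ids, site_label = site, region_label = region,
                 latitude = lat, longitude = lon, year = 2015L,
                 building_label = NA_character_)
}
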