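test_that("centroid great-circle distances match an independent haversine", {
  meta <- simple_meta(
    c("a1", "a2", "b1", "b2"),
    region = c("cny", "cny", "ma", "ma"),
    lat = c(41.9, 42.1, 41.9, 42.1),
    lon = c(-77.1, -76.9, -71.1, -70.9))
  d <- geo_distance_matrix(meta)
  expect_equal(d$values["cny", "cny"], 0)
  expect_equal(d$values["cny", "ma"],
               haversine_oracle(42, -77, 42, -71), tolerance = 1e-6)

  anti <- simple_meta(c("n", "s"), region = c("n", "s"),
                      lat = c(0, 0), lon = c(0, 180))
  da <- geo_distance_matrix(anti)
  expect_equal(da$values["n", "s"], pi * 6371.0088, tolerance = 1e-6)

  bad <- simple_meta("x", "r", NA_real_, -76)
  expect_error(geo_distance_matrix(bad), "without coordinates")
})

test_that("F_ST linearization has the documented fixed points", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(0.0525), 0.0525 / 0.9475, tolerance = 1e-12)
  expect_identical(linearize_fst(1), Inf)
  expect_true(all(diff(linearize_fst(seq(0, 0.9, 0.01))) > 0))  # monotone
})

pm_from_pairs <- function(labels, fill) {
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  m[upper.tri(m)] <- fill
  m <- m + t(m)
  m
}

test_that("the IBD regression recovers exact linear relationships", {
  labels <- sprintf("p%d", 1:5)
  km <- pm_from_pairs(labels, c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  # y = 2x through the linearized values
  lin <- 2 * km[upper.tri(km)]
  fst_lin <- lin / (1 + lin)   # invert the linearization
  fst <- pm_from_pairs(labels, fst_lin)
  res <- suppressWarnings(   # lm flags the intentionally perfect fit
    ibd_regression(pairwise_matrix(fst, "fst_nuclear"),
                   pairwise_matrix(km, "geo_km")))
  expect_equal(res$slope_b, 2, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)

  # zero-noise regeneration of a printed-scale fit: y = 1.27e-4 x - 0.01
  km2 <- pm_from_pairs(labels, seq(100, 1000, length.out = 10))
  lin2 <- 1.27e-4 * km2[upper.tri(km2)] - 0.01
  fst2 <- pm_from_pairs(labels, lin2 / (1 + lin2))
  res2 <- suppressWarnings(
    ibd_regression(pairwise_matrix(fst2, "fst_nuclear"),
                   pairwise_matrix(km2, "geo_km")))
  expect_equal(res2$slope_b, 1.27e-4, tolerance = 1e-10)
  expect_equal(res2$intercept, -0.01, tolerance = 1e-10)
  expect_identical(res2$n_pairs, 10L)
})

test_that("the Mantel permutation p-value is seeded and sane", {
  labels <- sprintf("p%d", 1:6)
  set.seed(5)
  km <- pm_from_pairs(labels, runif(15, 10, 500))
  lin <- 1e-3 * km[upper.tri(km)] + rnorm(15, 0, 0.005)
  fst <- pm_from_pairs(labels, pmax(lin / (1 + lin), 0))
  a <- ibd_regression(pairwise_matrix(fst, "f"), pairwise_matrix(km, "g"),
                      permutations = 499, seed = 11)
  b <- ibd_regression(pairwise_matrix(fst, "f"), pairwise_matrix(km, "g"),
                      permutations = 499, seed = 11)
  expect_identical(a$mantel_p, b$mantel_p)
  expect_lt(a$mantel_p, 0.05)
})

test_that("Rousset sigma inverts exactly and scales as De^(-1/2)", {
  for (b in c(1e-5, 1.27e-4, 0.0021)) {
    for (De in c(500, 1080, 2500)) {
      est <- rousset_sigma(b, De)
      b_back <- 1 / (4 * pi * De * (est$sigma_m / 1000)^2)
      expect_equal(b_back, b, tolerance = 1e-12)
    }
  }
  s1 <- rousset_sigma(1.27e-4, 500)$sigma_m
  s4 <- rousset_sigma(1.27e-4, 2000)$sigma_m
  expect_equal(s1 / s4, 2, tolerance = 1e-12)
  expect_error(rousset_sigma(-1e-4, 1080), "not positive")
  expect_error(rousset_sigma(0, 1080), "not positive")
})

test_that("the mito/nuclear F_ST expectation is a monotone [0,1] bijection", {
  expect_equal(expected_mito_fst(0), 0)
  expect_equal(expected_mito_fst(1), 1)
  grid <- seq(0, 1, length.out = 1000)
  vals <- expected_mito_fst(grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(expected_mito_fst(0.0525), 4 * 0.0525 / (1 + 3 * 0.0525),
               tolerance = 1e-12)
  expect_error(expected_mito_fst(1.2), "must lie")
  expect_error(expected_mito_fst(-0.1), "must lie")
})

test_that("the sex-bias t-test matches the closed form on a 10-pair table", {
  labels <- sprintf("p%d", 1:5)
  set.seed(8)
  fn <- pm_from_pairs(labels, runif(10, 0.02, 0.1))
  diffs <- rnorm(10, -0.05, 0.03)
  fm_vals <- expected_mito_fst(fn[upper.tri(fn)]) + diffs
  fm <- pm_from_pairs(labels, fm_vals)
  res <- sex_bias_test(pairwise_matrix(fn, "fst_nuclear"),
                       pairwise_matrix(fm, "fst_mito"))
  d <- res$pairs$difference
  expect_equal(res$t_statistic, mean(d) / (sd(d) / sqrt(10)),
               tolerance = 1e-10)
  expect_identical(res$df, 9)
  expect_equal(sort(d), sort(diffs), tolerance = 1e-12)
})

test_that("sex-bias degenerate inputs are handled explicitly", {
  labels <- sprintf("p%d", 1:5)
  fn <- pm_from_pairs(labels, rep(0.1, 10))
  fm_eq <- pm_from_pairs(labels, expected_mito_fst(rep(0.1, 10)))
  res <- sex_bias_test(pairwise_matrix(fn, "fst_nuclear"),
                       pairwise_matrix(fm_eq, "fst_mito"))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_identical(res$direction, "none")

  fm_const <- pm_from_pairs(labels, expected_mito_fst(rep(0.1, 10)) + 0.05)
  expect_warning(
    res2 <- sex_bias_test(pairwise_matrix(fn, "fst_nuclear"),
                          pairwise_matrix(fm_const, "fst_mito")),
    "infinite")
  expect_true(is.infinite(res2$t_statistic))
})
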