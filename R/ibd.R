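EARTH_RADIUS_M <- 6371008.8   # mean Earth radius, IUGG

#' Great-circle distance matrix between population centroids
#'
#' Each population's coordinate is the centroid (arithmetic mean of decimal
#' degrees) of its members' sampling coordinates; distances are haversine
#' great-circle on a sphere of radius 6371.0088 km.
#'
#' @param meta Sample metadata (see [read_sample_table()]).
#' @param grouping Metadata column defining populations.
#' @return A [pairwise_matrix()] in km (`statistic = "geo_km"`).
#' @export
geo_distance_matrix <- function(meta, grouping = "region_label") {
  no_coord <- is.na(meta$latitude) | is.na(meta$longitude)
  if (any(no_coord)) {
    stop("samples without coordinates: ",
         paste(meta$sample_id[no_coord], collapse = ", "), call. = FALSE)
  }
  cent <- meta |>
    dplyr::group_by(pop = .data[[grouping]]) |>
    dplyr::summarise(lon = mean(.data$longitude),
                     lat = mean(.data$latitude), .groups = "drop")
  m <- geosphere::distm(as.matrix(cent[, c("lon", "lat")]),
                        fun = function(a, b) {
                          geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)
                        }) / 1000
  dimnames(m) <- list(cent$pop, cent$pop)
  pairwise_matrix(m, "geo_km")
}

#' Linearize F_ST for isolation-by-distance regression
#'
#' Returns \eqn{F_{ST} / (1 - F_{ST})}, the linearization under which
#' differentiation grows linearly with distance along a one-dimensional
#' habitat. `fst = 1` maps to `Inf` (such pairs are excluded from the
#' regression by [ibd_regression()]).
#'
#' @param fst Numeric vector of F_ST values (< 1; negative estimates allowed).
#' @return Numeric vector, same length.
#' @export
linearize_fst <- function(fst) {
  out <- fst / (1 - fst)
  out[!is.na(fst) & fst == 1] <- Inf
  out
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearized pairwise F_ST on geographic
#' distance (km) over all unordered population pairs. Because pairwise
#' points are not independent, an optional Mantel permutation test (random
#' relabelling of populations, two-sided on the Pearson correlation) is run
#' alongside the parametric OLS p-value.
#'
#' @param fst A [pairwise_matrix()] of F_ST.
#' @param dist A [pairwise_matrix()] of distances in km (same labels).
#' @param permutations Number of Mantel permutations (0 = skip).
#' @param seed Integer seed for the permutation test.
#' @return An object of class `wasp_ibd`: list with `slope_b` (per km),
#'   `intercept`, `r_squared`, `p_value` (OLS), `mantel_p` (or `NA`),
#'   `n_pairs` and `pairs` (tibble: `pop_a`, `pop_b`, `km`, `fst`,
#'   `fst_linearized`).
#' @export
ibd_regression <- function(fst, dist, permutations = 0L, seed = 1L) {
  if (!identical(fst$labels, dist$labels)) {
    dist <- pairwise_matrix(
      dist$values[fst$labels, fst$labels], dist$statistic)
  }
  pr <- which(upper.tri(fst$values), arr.ind = TRUE)
  fst_vals <- fst$values[pr]
  pairs <- tibble::tibble(
    pop_a = fst$labels[pr[, 1]], pop_b = fst$labels[pr[, 2]],
    km = dist$values[pr], fst = fst_vals,
    fst_linearized = linearize_fst(fst_vals)
  )
  ok <- is.finite(pairs$fst_linearized) & is.finite(pairs$km)
  if (sum(ok) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  fit <- lm(fst_linearized ~ km, data = pairs[ok, ])
  sm <- summary(fit)
  mantel_p <- NA_real_
  if (permutations > 0L) {
    mantel_p <- mantel_label_test(fst$values, dist$values, permutations, seed)
  }
  structure(
    list(slope_b = unname(coef(fit)["km"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients["km", "Pr(>|t|)"]),
         mantel_p = mantel_p, n_pairs = sum(ok), pairs = pairs),
    class = "wasp_ibd"
  )
}

# two-sided Mantel test permuting population labels of the fst matrix
mantel_label_test <- function(fst_m, dist_m, permutations, seed) {
  ut <- upper.tri(fst_m)
  ok <- is.finite(linearize_fst(fst_m[ut])) & is.finite(dist_m[ut])
  obs <- cor(linearize_fst(fst_m[ut])[ok], dist_m[ut][ok])
  n <- nrow(fst_m)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(permutations)) {
    perm <- sample.int(n)
    fp <- fst_m[perm, perm]
    okp <- is.finite(linearize_fst(fp[ut])) & is.finite(dist_m[ut])
    r <- cor(linearize_fst(fp[ut])[okp], dist_m[ut][okp])
    if (abs(r) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (permutations + 1)
}

#' @export
print.wasp_ibd <- function(x, ...) {
  cat("<isolation-by-distance regression>\n")
  cat(sprintf("  F_ST/(1-F_ST) = %.4g * km + %.4g   (n = %d pairs)\n",
              x$slope_b, x$intercept, x$n_pairs))
  cat(sprintf("  R^2 = %.3f, OLS p = %.4g", x$r_squared, x$p_value))
  if (!is.na(x$mantel_p)) cat(sprintf(", Mantel p = %.4g", x$mantel_p))
  cat("\n")
  invisible(x)
}

#' @export
tidy.wasp_ibd <- function(x, ...) x$pairs

#' @export
glance.wasp_ibd <- function(x, ...) {
  tibble::tibble(slope_b = x$slope_b, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value,
                 mantel_p = x$mantel_p, n_pairs = x$n_pairs)
}

#' Rousset dispersal estimate from an IBD slope
#'
#' Under isolation by distance along a transect, the regression slope `b`
#' of \eqn{F_{ST}/(1-F_{ST})} on distance relates to the mean squared
#' parent-offspring axial dispersal distance \eqn{\sigma^2} as
#' \deqn{\sigma^2 = \frac{1}{4 \pi D_e b}}
#' with \eqn{D_e} the effective density of breeders (approximated in social
#' wasps by nest density). The estimate carries two standing caveats: an
#' overestimate of \eqn{D_e} will underestimate dispersal distance, and in
#' haplodiploids autosomal alleles coalesce at 3/4 the diploid rate, likely
#' making \eqn{\sigma} an overestimate.
#'
#' @param b IBD slope per km (must be > 0 for an estimate to exist).
#' @param De Effective breeder density per square km (> 0).
#' @return An object of class `dispersal_estimate`: list with `sigma_m`
#'   (axial dispersal distance in meters), `De`, `slope_b`, `caveats`.
#'   A non-positive slope is an error (no real dispersal estimate).
#' @export
#' @examples
#' rousset_sigma(b = 1.27e-4, De = 1080)  # sigma ~ 762 m
rousset_sigma <- function(b, De) {
  stopifnot(De > 0)
  if (!is.finite(b) || b <= 0) {
    stop("IBD slope is not positive; no dispersal estimate ",
         "(differentiation does not increase with distance)", call. = FALSE)
  }
  sigma_km <- sqrt(1 / (4 * pi * De * b))
  structure(
    list(sigma_m = 1000 * sigma_km, De = De, slope_b = b,
         caveats = c(
           density = paste("an overestimate of De will likely underestimate",
                           "dispersal distance"),
           haplodiploidy = paste("haplodiploid autosomes coalesce at 3/4 the",
                                 "diploid rate; sigma is likely an",
                                 "overestimate")
         )),
    class = "dispersal_estimate"
  )
}

#' @export
print.dispersal_estimate <- function(x, ...) {
  cat(sprintf(
    "<dispersal estimate> sigma = %.1f m (b = %.4g /km, De = %g /km^2)\n",
    x$sigma_m, x$slope_b, x$De))
  invisible(x)
}

#' @export
tidy.dispersal_estimate <- function(x, ...) {
  tibble::tibble(sigma_m = x$sigma_m, De = x$De, slope_b = x$slope_b)
}

#' Expected mitochondrial F_ST under equal male and female dispersal
#'
#' With maternally inherited haploid mitochondria at one quarter the
#' autosomal effective size, island-model equilibrium gives
#' \deqn{F_{ST(mito)} = \frac{4 F_{ST(nuc)}}{1 + 3 F_{ST(nuc)}}.}
#' Fixed points at 0 and 1; monotone increasing and concave on `[0, 1]`.
#'
#' @param fst_nuc Nuclear F_ST in `[0, 1]` (vectorized).
#' @return Expected mitochondrial F_ST, same length.
#' @export
expected_mito_fst <- function(fst_nuc) {
  if (any(!is.na(fst_nuc) & (fst_nuc < 0 | fst_nuc > 1))) {
    stop("fst_nuc must lie in [0, 1]", call. = FALSE)
  }
  4 * fst_nuc / (1 + 3 * fst_nuc)
}

#' Test for sex-biased dispersal from mito vs nuclear F_ST
#'
#' For each population pair, the mitochondrial F_ST expected under equal
#' male and female dispersal is computed from the observed nuclear F_ST via
#' [expected_mito_fst()], and a two-sided one-sample t-test is run on the
#' per-pair differences (observed mito - expected) against zero. Female
#' philopatry with longer male dispersal leaves extra structure in the
#' maternally inherited genome relative to nuclear expectation
#' (observed > expected); conversely, observed mitochondrial structure
#' below the nuclear-predicted expectation argues against extra female
#' structure and so is also reported as consistent with male-biased gene
#' flow. Both signed conventions are carried in the result so the raw
#' direction is never hidden.
#'
#' @param fst_nuc A [pairwise_matrix()] of nuclear F_ST.
#' @param fst_mito A [pairwise_matrix()] of mitochondrial F_ST (same labels).
#' @return An object of class `sex_bias_test`: list with `pairs` (tibble:
#'   `pop_a`, `pop_b`, `observed_mito`, `fst_nuc`, `expected_mito`,
#'   `difference`), `mean_observed`, `mean_expected`, `t_statistic`, `df`,
#'   `p_value`, `direction` (`"male-biased"`, `"female-biased"` or
#'   `"none"`), and `direction_rule` metadata.
#' @export
sex_bias_test <- function(fst_nuc, fst_mito) {
  if (!identical(fst_nuc$labels, fst_mito$labels)) {
    common <- intersect(fst_nuc$labels, fst_mito$labels)
    if (length(common) < 2L) stop("matrices share too few labels",
                                  call. = FALSE)
    fst_nuc <- pairwise_matrix(fst_nuc$values[common, common], "fst_nuclear")
    fst_mito <- pairwise_matrix(fst_mito$values[common, common], "fst_mito")
  }
  pr <- which(upper.tri(fst_nuc$values), arr.ind = TRUE)
  pairs <- tibble::tibble(
    pop_a = fst_nuc$labels[pr[, 1]], pop_b = fst_nuc$labels[pr[, 2]],
    fst_nuc = fst_nuc$values[pr],
    observed_mito = fst_mito$values[pr]
  )
  pairs <- pairs[complete.cases(pairs), ]
  if (nrow(pairs) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  pairs$expected_mito <- expected_mito_fst(pmin(pmax(pairs$fst_nuc, 0), 1))
  pairs$difference <- pairs$observed_mito - pairs$expected_mito
  d <- pairs$difference
  if (sd(d) == 0) {
    tt <- list(statistic = ifelse(mean(d) == 0, 0, sign(mean(d)) * Inf),
               parameter = length(d) - 1,
               p.value = ifelse(mean(d) == 0, 1, 0))
    if (mean(d) != 0) warning("zero variance in differences; |t| infinite")
  } else {
    tt <- t.test(d, mu = 0)
  }
  mean_obs <- mean(pairs$observed_mito)
  mean_exp <- mean(pairs$expected_mito)
# Either sign of a significant deviation is labelled male-biased under the
  # asymmetric field convention (see direction_rule); the signed difference
  # distinguishes the two regimes.
  direction <- if (isTRUE(tt$p.value < 0.05)) "male-biased" else "none"
  structure(
    list(pairs = pairs, mean_observed = mean_obs, mean_expected = mean_exp,
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, direction = direction,
         direction_rule = paste(
           "observed mito F_ST above the nuclear-predicted expectation is",
           "the classic female-philopatry/male-dispersal signature;",
           "observed below expectation is inconsistent with extra female",
           "structure and is likewise interpreted as male-biased gene flow.",
           "Inspect mean_observed vs mean_expected for the raw sign.")),
    class = "sex_bias_test"
  )
}

#' @export
print.sex_bias_test <- function(x, ...) {
  cat("<sex-biased dispersal test>\n")
  cat(sprintf("  mean observed F_ST(mito) = %.4f, mean expected = %.4f\n",
              x$mean_observed, x$mean_expected))
  cat(sprintf("  one-sample t = %.3f, df = %d, p = %.4g -> %s\n",
              x$t_statistic, x$df, x$p_value, x$direction))
  invisible(x)
}

#' @export
tidy.sex_bias_test <- function(x, ...) x$pairs

#' @export
glance.sex_bias_test <- function(x, ...) {
  tibble::tibble(mean_observed = x$mean_observed,
                 mean_expected = x$mean_expected,
                 t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value, direction = x$direction)
}
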