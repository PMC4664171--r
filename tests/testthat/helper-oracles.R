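# Independent oracles used to cross-check the package's statistics.
# Each deliberately takes a different route than the implementation.

# Step-up BH applied by hand: sort, compare p_(i) * m / i, enforce
# monotonicity from the largest rank down, map back to input order.
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(1, adj)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

# OLS via stats::lm (the implementation uses closed-form vectorised sums).
lm_oracle <- function(beta, dosage) {
  fit <- summary(lm(beta ~ dosage))
  list(slope = unname(coef(fit)[2, 1]),
       intercept = unname(coef(fit)[1, 1]),
       p = unname(coef(fit)[2, 4]),
       r_squared = fit$r.squared)
}

# Monte-Carlo permutation p-value for the regression slope.
perm_p_slope <- function(beta, dosage, n_perm = 10000) {
  obs <- abs(cor(beta, dosage))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(cor(beta, sample(dosage))) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis statistic.
perm_p_kw <- function(values, groups, n_perm = 10000) {
  obs <- kw_stat(values, groups)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (kw_stat(values, sample(groups)) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Kruskal-Wallis H with tie correction, from the definition.
kw_stat <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exhaustive permutation p for Spearman rho at small n (no ties).
spearman_perm_p <- function(x, y) {
  stopifnot(length(x) <= 8, !anyDuplicated(x), !anyDuplicated(y))
  rho_obs <- abs(cor(x, y, method = "spearman"))
  perms <- permutations_of(length(y))
  ry <- rank(y)
  rx <- rank(x)
  rhos <- apply(perms, 1, function(idx) abs(cor(rx, ry[idx])))
  mean(rhos >= rho_obs - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# Definitional Grubbs statistic.
grubbs_g <- function(x) max(abs(x - mean(x))) / sd(x)

# Small synthetic cohort helper for scan-level tests: one locus, a few
# probes, optional planted effect at probe 1.
tiny_cohort <- function(n = 60, n_probes = 5, maf = 0.4, effect = 0,
                        noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  loci <- oa_loci()[oa_loci()$snp_id == "rs3204689", ]
  planted <- default_planted_effects(effect)[
    default_planted_effects(effect)$locus_id == "ALDH1A2", ]
  cfg <- sim_config(
    n_oa_knee = n - 10, n_oa_hip = 5, n_nof = 5,
    loci = dplyr::mutate(loci, sim_maf = maf,
                         n_region_probes = as.integer(n_probes)),
    planted = if (effect != 0) planted else planted[0, ],
    group_offsets = default_group_offsets()[0, ],
    sex_offsets = default_sex_offsets()[0, ],
    noise_sd_logit = noise_sd)
  simulate_cohort(cfg, seed = seed)
}
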