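test_that("dosage regression matches the lm route on fixed and random data", {
  beta <- c(0.20, 0.31, 0.39, 0.21, 0.29, 0.41)
  dosage <- c(0, 1, 2, 0, 1, 2)
  fit <- dosage_regression(beta, dosage)
  oracle <- lm_oracle(beta, dosage)
  expect_equal(fit$slope, oracle$slope)
  expect_equal(fit$intercept, oracle$intercept)
  expect_equal(fit$p_raw, oracle$p)
  expect_equal(fit$r_squared, oracle$r_squared)
  expect_equal(fit$status, "ok")

  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    d <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (length(unique(d)) < 2) next
    b <- plogis(rnorm(n, 0, 1) - 0.2 * d)
    fit <- dosage_regression(b, d)
    oracle <- lm_oracle(b, d)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$p_raw, oracle$p, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("dosage regression handles missing values by pairwise deletion", {
  set.seed(3)
  d <- c(rbinom(20, 2, 0.4), NA, 1)
  b <- c(runif(20), 0.5, NA)
  fit <- dosage_regression(b, d)
  keep <- !is.na(b) & !is.na(d)
  oracle <- lm_oracle(b[keep], d[keep])
  expect_equal(fit$n_used, sum(keep))
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
})

test_that("degenerate regression inputs are flagged, not fatal", {
  expect_equal(dosage_regression(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                                 c(0, 1, 2, 0, 1, 2))$slope, 0)
  expect_equal(dosage_regression(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                                 c(0, 1, 2, 0, 1, 2))$p_raw, 1)
  expect_equal(dosage_regression(runif(6), rep(1, 6))$status, "monomorphic")
  expect_equal(dosage_regression(c(0.1, 0.2), c(0, 1))$status,
               "insufficient_data")
  expect_error(dosage_regression(runif(4), c(0, 1, 2, 3)), "0, 1 or 2")
})

test_that("regression p agrees with a permutation test at n = 9", {
  set.seed(21)
  d <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  b <- plogis(rnorm(9, 0, 0.4) - 0.35 * d)
  p_model <- dosage_regression(b, d)$p_raw
  p_perm <- perm_p_slope(b, d, n_perm = 20000)
  # permutation tests |r|, identical ordering to |t| for simple OLS
  expect_lt(abs(p_model - p_perm), 0.02)
})

test_that("BH adjustment matches a hand-applied step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.04, m = 1), 0.04)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(5)
  for (i in 1:25) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- bh_adjust(p, m)
    expect_equal(adj, bh_oracle(p, m))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # monotone in the sorted order
    expect_false(is.unsorted(adj[order(p)]))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "smaller")
})

test_that("region scan finds planted probes and only those", {
  cohort <- tiny_cohort(n = 99, n_probes = 40, maf = 0.4, effect = -0.5,
                        noise_sd = 0.12, seed = 8)
  locus <- cohort$loci
  probes <- select_probes(cohort$manifest, locus)
  res <- scan_locus(cohort, locus, probes)
  expect_equal(nrow(res), 40)
  hit <- dplyr::filter(res, significant)
  expect_equal(hit$probe_id, "cg12031962")
  expect_true(all(res$p_adj >= res$p_raw - 1e-12, na.rm = TRUE))
  # risk allele (major C) carries the negative effect
  expect_equal(hit$direction_vs_risk, "lower")
  expect_gt(hit$slope, 0)  # slope per minor allele flips sign
})

test_that("empty or degenerate strata are flagged without aborting", {
  cohort <- tiny_cohort(n = 30, n_probes = 4, seed = 2)
  locus <- cohort$loci
  probes <- select_probes(cohort$manifest, locus)
  expect_warning(
    res <- scan_locus(cohort, locus, probes, sample_ids = character(0),
                      stratum_label = "hands"),
    "matches no samples")
  expect_equal(nrow(res), 0)

  res2 <- scan_locus(cohort, locus, probes,
                     sample_ids = cohort$samples$sample_id[1:2])
  expect_true(all(res2$status == "insufficient_data"))
  expect_true(all(!res2$significant))

  mono <- cohort
  mono$dosages$rs3204689 <- rep(1L, nrow(mono$dosages))
  res3 <- scan_locus(mono, locus, probes)
  expect_true(all(res3$status == "monomorphic"))
})

test_that("stratified passes detect effects where they are planted", {
  cohort <- tiny_cohort(n = 99, n_probes = 10, maf = 0.4, effect = -0.5,
                        noise_sd = 0.12, seed = 13)
  scan <- scan_strata(cohort, passes = c("all", "OA", "OA_knee"))
  res <- tidy(scan)
  for (pass in c("all", "OA", "OA_knee")) {
    expect_true("cg12031962" %in%
                  res$probe_id[res$significant &
                                 res$stratum_label == pass])
  }
  # each pass is corrected over the full region family
  expect_equal(unique(table(res$stratum_label)),
               nrow(select_probes(cohort$manifest, scan$loci[1, ])))
})

test_that("an effect confined to knees attenuates in the pooled pass", {
  # plant the effect only in knee samples by zeroing the genotype effect
  # elsewhere: simulate two groups and splice
  set.seed(17)
  base <- tiny_cohort(n = 99, n_probes = 8, maf = 0.4, effect = -0.6,
                      noise_sd = 0.12, seed = 17)
  knee <- base$samples$joint == "knee" & base$samples$status == "OA"
  d <- base$dosages$rs3204689
  d_risk <- 2 - d  # risk allele is major for rs3204689
  b <- base$betas$cg12031962
  # overwrite non-knee samples with genotype-free methylation
  b[!knee] <- plogis(qlogis(b[!knee]) + 0.6 * d_risk[!knee])
  base$betas$cg12031962 <- b
  scan <- scan_strata(base, passes = c("all", "OA_knee"))
  res <- tidy(scan)
  p_knee <- res$p_raw[res$probe_id == "cg12031962" &
                        res$stratum_label == "OA_knee"]
  p_all <- res$p_raw[res$probe_id == "cg12031962" &
                       res$stratum_label == "all"]
  expect_lt(p_knee, p_all)
  expect_lt(p_knee, 0.05)
})

test_that("scan results are bit-identical under a repeated seed", {
  c1 <- simulate_cohort(sim_config(seed = 99))
  c2 <- simulate_cohort(sim_config(seed = 99))
  expect_identical(c1$betas, c2$betas)
  s1 <- scan_strata(c1, passes = "all")
  s2 <- scan_strata(c2, passes = "all")
  expect_identical(tidy(s1), tidy(s2))
})

test_that("direction labels flip exactly when the risk allele is major", {
  set.seed(23)
  d <- rbinom(50, 2, 0.4)
  b <- plogis(-0.4 * d + rnorm(50, 0, 0.2))
  slope <- dosage_regression(b, d)$slope
  # risk = minor: direction follows the minor-allele slope
  minor_risk <- tibble::tibble(
    locus_id = "L", snp_id = "rs1", position = 100, minor_allele = "A",
    risk_allele = "A")
  major_risk <- dplyr::mutate(minor_risk, risk_allele = "G")
  cohort <- list(
    samples = tibble::tibble(sample_id = as.character(1:50),
                             status = "OA", joint = "knee", sex = "male"),
    dosages = tibble::tibble(sample_id = as.character(1:50), rs1 = d),
    betas = tibble::tibble(sample_id = as.character(1:50), cg1 = b))
  probes <- tibble::tibble(probe_id = "cg1", chromosome = "1",
                           position = 50)
  lab <- function(locus) {
    scan_locus(cohort, locus, probes)$direction_vs_risk
  }
  expect_lt(slope, 0)
  expect_equal(lab(minor_risk), "lower")
  expect_equal(lab(major_risk), "higher")
})

test_that("group methylation comparison behaves across group structures", {
  # identical distributions -> H = 0, p = 1
  d <- tibble::tibble(beta = rep(c(0.4, 0.5, 0.6), 3),
                      grp = rep(c("OA_knee", "OA_hip", "NOF"), each = 3))
  cmp <- group_methylation_comparison(d, beta, grp)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  # NOF shifted down at study group sizes -> NOF mean lowest, p < 0.05
  set.seed(31)
  d2 <- tibble::tibble(
    grp = rep(c("NOF", "OA_knee", "OA_hip"), c(19, 63, 17)),
    beta = plogis(rnorm(99, 0, 0.15) - 0.5 * (rep(c(1, 0, 0),
                                                  c(19, 63, 17)))))
  cmp2 <- group_methylation_comparison(d2, beta, grp)
  gm <- cmp2$group_means[[1]]
  expect_equal(gm$group[which.min(gm$mean)], "NOF")
  expect_lt(cmp2$p_value, 0.05)

  # two groups: Kruskal-Wallis p equals the rank-sum p
  set.seed(32)
  d3 <- tibble::tibble(beta = runif(24),
                       grp = rep(c("OA_knee", "NOF"), each = 12))
  cmp3 <- group_methylation_comparison(d3, beta, grp)
  w <- wilcox.test(beta ~ grp, data = d3, exact = FALSE, correct = FALSE)
  expect_equal(cmp3$p_value, w$p.value, tolerance = 1e-10)

  # a 1-sample group is dropped with a warning
  d4 <- dplyr::bind_rows(d3, tibble::tibble(beta = 0.5, grp = "OA_hip"))
  expect_warning(cmp4 <- group_methylation_comparison(d4, beta, grp),
                 "OA_hip")
  expect_equal(cmp4$n_groups, 2)
})

test_that("variance explained is 100 x squared Pearson correlation", {
  d <- c(0, 1, 2, 0, 1, 2)
  expect_equal(variance_explained(c(0.2, 0.3, 0.4, 0.2, 0.3, 0.4), d), 100)
  expect_equal(variance_explained(rep(0.5, 6), d), 0)
  set.seed(41)
  for (i in 1:10) {
    dd <- rbinom(30, 2, 0.4)
    b <- runif(30)
    expect_equal(variance_explained(b, dd), 100 * cor(b, dd)^2,
                 tolerance = 1e-10)
  }
})
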