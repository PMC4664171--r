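test_that("genotype simulation follows Hardy-Weinberg proportions", {
  expect_error(simulate_genotypes(10, 0), "\\(0, 1\\)")
  expect_error(simulate_genotypes(10, 1), "\\(0, 1\\)")
  # vanishing MAF limit: all homozygous major
  expect_true(all(simulate_genotypes(1000, 1e-9, seed = 1) == 0))

  d <- simulate_genotypes(10000, 0.5, seed = 2)
  expect_lt(abs(mean(d) - 1), 3 * sqrt(0.5 / 10000))

  d <- simulate_genotypes(10000, 0.3, seed = 3)
  obs <- tabulate(d + 1, 3)
  expected <- 10000 * c(0.49, 0.42, 0.09)
  chisq <- sum((obs - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 2))
})

test_that("methylation simulation respects the logit-scale model", {
  # no effect, no noise -> constant inverse-logit(baseline)
  b <- simulate_methylation(c(0, 1, 2), baseline_logit = 0.5,
                            noise_sd = 0)
  expect_equal(b, rep(plogis(0.5), 3))
  # deterministic allelic effect
  b2 <- simulate_methylation(c(0, 1, 2), 0, effect_logit = -0.4,
                             noise_sd = 0)
  expect_equal(b2, plogis(-0.4 * c(0, 1, 2)))
  # bounded in (0, 1) at extreme parameters
  x <- simulate_methylation(rep(2, 1e5), baseline_logit = 30,
                            effect_logit = 10, noise_sd = 50, seed = 4)
  expect_true(all(x > 0 & x < 1))
})

test_that("pyro duplicates reproduce the Gaussian-tail QC failure rate", {
  # zero replicate noise -> identical duplicates, all pass
  p0 <- simulate_pyro(runif(50), replicate_sd = 0, seed = 5)
  expect_equal(p0$rep1, p0$rep2)
  expect_true(all(qc_duplicates(p0)$qc_pass))

  # sd = 4: P(fail) = P(|N(0, 2 sd^2)| > 5), away from the truncation
  # boundaries
  sd_rep <- 4
  n <- 40000
  p <- simulate_pyro(rep(0.5, n), replicate_sd = sd_rep, seed = 6)
  fail_obs <- mean(abs(p$rep1 - p$rep2) > 5)
  fail_theory <- 2 * pnorm(5 / sqrt(2 * sd_rep^2), lower.tail = FALSE)
  expect_lt(abs(fail_obs - fail_theory),
            4 * sqrt(fail_theory * (1 - fail_theory) / n))

  # truncation keeps the scale
  lo <- simulate_pyro(rep(0, 1000), replicate_sd = 10, seed = 7)
  expect_true(all(lo$rep1 >= 0 & lo$rep2 >= 0))
  hi <- simulate_pyro(rep(1, 1000), replicate_sd = 10, seed = 8)
  expect_true(all(hi$rep1 <= 100 & hi$rep2 <= 100))
})

test_that("expression simulation carries the planted link", {
  # zero link: no methylation-expression correlation on average
  set.seed(9)
  rhos <- replicate(30, {
    beta <- runif(29)
    ct <- simulate_expression(beta, link_slope = 0, noise_sd = 0.5)
    methylation_expression_correlation(
      relative_expression(ct)$rel_expr, beta)$rho
  })
  expect_lt(abs(mean(rhos)), 0.12)

  # positive methylation->Ct link: negative correlation recovered
  set.seed(10)
  neg <- replicate(20, {
    beta <- runif(29)
    ct <- simulate_expression(beta, link_slope = 4, noise_sd = 0.3)
    methylation_expression_correlation(
      relative_expression(ct)$rel_expr, beta)$rho
  })
  expect_true(all(neg < 0))

  # fixed seed -> bitwise identical tables
  expect_identical(simulate_expression(runif(5), seed = 11),
                   simulate_expression(runif(5), seed = 11))
})

test_that("the default cohort matches the study composition", {
  cohort <- simulate_cohort(sim_config(seed = 20))
  expect_equal(nrow(cohort$samples), 99)
  expect_equal(sum(cohort$samples$status == "OA" &
                     cohort$samples$joint == "knee"), 63)
  expect_equal(sum(cohort$samples$status == "OA" &
                     cohort$samples$joint == "hip"), 17)
  expect_equal(sum(cohort$samples$status == "NOF"), 19)
  expect_true(all(cohort$samples$joint[cohort$samples$status == "NOF"]
                  %in% c("hip", "none")))

  # per-region non-polymorphic probe counts equal the panel's m values
  loci <- build_windows(cohort$loci)
  m <- vapply(seq_len(nrow(loci)), function(i) {
    nrow(select_probes(cohort$manifest, loci[i, ]))
  }, integer(1))
  expect_equal(m, loci$n_region_probes)

  # all betas strictly inside (0, 1), all dosages in {0, 1, 2}
  bm <- as.matrix(cohort$betas[-1])
  expect_true(all(bm > 0 & bm < 1))
  expect_true(all(as.matrix(cohort$dosages[-1]) %in% 0:2))
})

test_that("the truth ledger round-trips every planted effect", {
  cfg <- sim_config(seed = 21)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$truth), nrow(cfg$planted))
  expect_true(all(cohort$truth$probe_id %in% cohort$manifest$probe_id))
  expect_equal(cohort$truth$effect_logit, cfg$planted$effect_logit)
  # planted probes sit at their catalogued positions
  pos <- cohort$manifest$position[match(cohort$truth$probe_id,
                                        cohort$manifest$probe_id)]
  expect_equal(pos, oa_meqtl_cpgs()$position[
    match(cohort$truth$probe_id, oa_meqtl_cpgs()$probe_id)])
  # beta-scale effect signs: negative per risk allele, flipped per minor
  # allele when the risk allele is major
  expect_true(all(cohort$truth$effect_beta_risk < 0))
  expect_equal(cohort$truth$effect_beta_minor < 0,
               cohort$truth$risk_is_minor)
})

test_that("the quadrature beta-scale slope matches a huge-sample fit", {
  cfg <- sim_config(seed = 22)
  cohort <- simulate_cohort(cfg)
  tr <- cohort$truth[cohort$truth$probe_id == "cg12031962", ]
  # simulate an enormous sample from the same generative law (no offsets
  # at this probe) and fit OLS
  set.seed(23)
  n <- 4e5
  d <- simulate_genotypes(n, tr$maf)
  d_risk <- 2 - d  # risk allele is major at this locus
  b <- simulate_methylation(d_risk, tr$baseline_logit, tr$effect_logit,
                            noise_sd = cfg$noise_sd_logit)
  slope_hat <- dosage_regression(b, d)$slope
  expect_equal(slope_hat, tr$effect_beta_minor, tolerance = 0.02)
})

test_that("cohort generation is reproducible and substreams are derived", {
  c1 <- simulate_cohort(sim_config(seed = 30))
  c2 <- simulate_cohort(sim_config(seed = 30))
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$betas, c2$betas)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(sim_config(seed = 31))
  expect_false(identical(c1$betas, c3$betas))
})
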