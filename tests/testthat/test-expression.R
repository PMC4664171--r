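ct_row <- function(target, hk) {
  tibble::tibble(sample_id = "s1", gene = "G", ct_target = target,
                 ct_18s = hk[1], ct_gapdh = hk[2], ct_hprt1 = hk[3])
}

test_that("2^-deltaCt relative expression follows the definition", {
  # target equal to the housekeeping mean -> 1
  expect_equal(relative_expression(ct_row(20, c(18, 20, 22)))$rel_expr, 1)
  # deltaCt = 5 -> 2^-5
  expect_equal(relative_expression(ct_row(25, c(18, 20, 22)))$rel_expr,
               0.03125)
  # monotone decreasing in target Ct
  targets <- seq(18, 30, by = 0.5)
  re <- vapply(targets, function(t) {
    relative_expression(ct_row(t, c(18, 20, 22)))$rel_expr
  }, numeric(1))
  expect_true(all(diff(re) < 0))
  expect_error(relative_expression(ct_row(-1, c(18, 20, 22))), "> 0")
})

test_that("relative expression is invariant to a global Ct shift", {
  set.seed(1)
  for (i in 1:10) {
    hk <- runif(3, 15, 25)
    t0 <- runif(1, 20, 30)
    c_shift <- runif(1, -3, 3)
    expect_equal(relative_expression(ct_row(t0, hk))$rel_expr,
                 relative_expression(ct_row(t0 + c_shift,
                                            hk + c_shift))$rel_expr,
                 tolerance = 1e-12)
  }
})

test_that("missing housekeeping values follow the configured policy", {
  r <- ct_row(25, c(18, 20, NA))
  expect_error(relative_expression(r), "housekeeping")
  out <- relative_expression(r, missing_hk = "mean_available")
  expect_equal(out$rel_expr, 2^-(25 - 19))
  expect_error(relative_expression(ct_row(25, c(18, NA, NA)),
                                   missing_hk = "mean_available"),
               "Fewer than 2")
})

test_that("Grubbs filter removes a gross outlier and only that", {
  out <- grubbs_filter(c(1.0, 1.1, 0.9, 1.05, 8.0))
  expect_equal(out$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # its G exceeded the tabulated critical value at n = 5
  x <- c(1.0, 1.1, 0.9, 1.05, 8.0)
  expect_gt(grubbs_g(x), 1.715)  # two-sided critical G, alpha 0.05, n 5
  # remaining values stay
  expect_true(all(!grubbs_filter(c(1.0, 1.1, 0.9, 1.05))$outlier))
  # constant input: zero spread, nothing removed
  expect_true(all(!grubbs_filter(rep(2, 5))$outlier))
})

test_that("the first Grubbs statistic equals the definitional maximum", {
  set.seed(14)
  for (i in 1:10) {
    x <- rlnorm(10)
    g_impl <- max(abs(x - mean(x))) / sd(x)  # what the filter computes
    expect_equal(g_impl, grubbs_g(x))
    # decision consistency: removal iff G > critical value
    out <- grubbs_filter(x)
    crit <- (9 / sqrt(10)) * sqrt(qt(0.0025, 8, lower.tail = FALSE)^2 /
                                    (8 + qt(0.0025, 8,
                                            lower.tail = FALSE)^2))
    expect_equal(any(out$outlier), grubbs_g(x) > crit)
  }
})

test_that("Grubbs removal is order-independent", {
  set.seed(15)
  x <- c(rnorm(8), 6, -5)
  ref <- sort(grubbs_filter(x)$value[grubbs_filter(x)$outlier])
  for (i in 1:5) {
    xs <- sample(x)
    expect_equal(sort(grubbs_filter(xs)$value[grubbs_filter(xs)$outlier]),
                 ref)
  }
})

test_that("Spearman correlation handles monotone, reversed and random pairs", {
  expect_equal(methylation_expression_correlation(
    c(1, 2, 3, 5, 9), c(0.1, 0.2, 0.3, 0.4, 0.9))$rho, 1)
  expect_equal(methylation_expression_correlation(
    c(1, 2, 3, 5, 9), c(0.9, 0.4, 0.3, 0.2, 0.1))$rho, -1)
  # invariant under strictly monotone transforms
  set.seed(20)
  x <- runif(12)
  y <- runif(12)
  base <- methylation_expression_correlation(x, y)$rho
  expect_equal(methylation_expression_correlation(exp(3 * x), y)$rho, base)
  expect_equal(methylation_expression_correlation(x, y^3)$rho, base)
  # constant input flagged
  expect_equal(methylation_expression_correlation(rep(1, 5),
                                                  runif(5))$status,
               "constant_input")
  expect_error(methylation_expression_correlation(1:3, 1:3), "4")
})

test_that("Spearman p agrees with exhaustive rank permutation at n = 8", {
  set.seed(22)
  x <- rnorm(8)
  y <- 0.6 * x + rnorm(8, 0, 0.8)
  p_model <- methylation_expression_correlation(x, y)$p_value
  p_exact <- spearman_perm_p(x, y)
  expect_lt(abs(p_model - p_exact), 0.02)
})

test_that("expression-by-genotype tests behave and detect a planted eQTL", {
  # identical group distributions -> KW p = 1
  same <- expression_by_genotype(rep(c(1, 2, 3), 3), rep(0:2, each = 3))
  expect_equal(same$p_value, 1)

  # two-group t-test equals the closed-form Welch computation
  set.seed(25)
  e <- rlnorm(20)
  g <- rep(c(0, 2), each = 10)
  tt <- expression_by_genotype(e, g, test = "t_test")
  x1 <- e[g == 0]
  x2 <- e[g == 2]
  se <- sqrt(var(x1) / 10 + var(x2) / 10)
  tstat <- (mean(x1) - mean(x2)) / se
  df <- se^4 / ((var(x1) / 10)^2 / 9 + (var(x2) / 10)^2 / 9)
  expect_equal(tt$statistic, tstat, tolerance = 1e-10)
  expect_equal(tt$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-10)

  # 30% expression drop per risk allele at n = 29: detected in the
  # majority of simulations
  hits <- 0L
  n_sim <- 100
  for (s in 1:n_sim) {
    set.seed(3000 + s)
    d <- rbinom(29, 2, 0.44)
    e <- rlnorm(29, meanlog = log(0.7) * d, sdlog = 0.3)
    p <- expression_by_genotype(e, d)$p_value
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.5)

  # group-size violations
  expect_equal(expression_by_genotype(c(1, 2, 3), c(0, 0, 2))$status,
               "not_testable")
})
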