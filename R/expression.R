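#' Relative gene expression by the 2^-deltaCt method
#'
#' Computes `2^-(Ct_target - mean(Ct_housekeeping))` per sample and gene,
#' with the housekeeping mean taken over the three reference-gene cycle
#' thresholds (18S, GAPDH, HPRT1 roles). Missing housekeeping values are
#' either rejected (`missing_hk = "error"`) or averaged over the available
#' ones when at least two are present (`"mean_available"`).
#'
#' @param ct Tibble with columns `sample_id`, `gene`, `ct_target`,
#'   `ct_18s`, `ct_gapdh`, `ct_hprt1` (cycle thresholds, finite and > 0).
#' @param missing_hk `"error"` (default) or `"mean_available"`.
#' @return `ct` with an added `rel_expr` column (dimensionless, > 0).
#' @examples
#' ct <- tibble::tibble(sample_id = "s1", gene = "ALDH1A2",
#'                      ct_target = 25, ct_18s = 18, ct_gapdh = 20,
#'                      ct_hprt1 = 22)
#' relative_expression(ct)   # 2^-(25 - 20) = 0.03125
#' @export
relative_expression <- function(ct, missing_hk = c("error",
                                                   "mean_available")) {
  missing_hk <- match.arg(missing_hk)
  hk_cols <- c("ct_18s", "ct_gapdh", "ct_hprt1")
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "gene", "ct_target", hk_cols) %in% names(ct)))
  vals <- as.matrix(ct[c("ct_target", hk_cols)])
  if (any(!is.na(vals) & (vals <= 0 | !is.finite(vals)))) {
    abort("Ct values must be finite and > 0.")
  }
  if (any(is.na(ct$ct_target))) abort("Missing target Ct value(s).")
  hk <- as.matrix(ct[hk_cols])
  n_hk <- rowSums(!is.na(hk))
  if (missing_hk == "error" && any(n_hk < 3)) {
    abort(sprintf("Missing housekeeping Ct in row(s): %s",
                  paste(head(which(n_hk < 3), 10), collapse = ", ")))
  }
  if (any(n_hk < 2)) {
    abort("Fewer than 2 housekeeping Ct values available in some rows.")
  }
  hk_mean <- rowMeans(hk, na.rm = TRUE)
  dplyr::mutate(tibble::as_tibble(ct),
                rel_expr = 2^-(.data$ct_target - hk_mean))
}

grubbs_critical <- function(n, alpha) {
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative two-sided Grubbs outlier filter
#'
#' Repeatedly applies the two-sided Grubbs test at level `alpha`: the value
#' with the largest `|x - mean| / sd` is removed if its G statistic exceeds
#' the t-distribution-based critical value, until no value does or fewer
#' than 3 remain. A zero-spread sample has no outliers.
#'
#' @param values Numeric vector (>= 3 values to test anything).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per input value: `value`, `outlier`
#'   (logical), `step` (removal iteration, `NA` if kept).
#' @examples
#' grubbs_filter(c(1.0, 1.1, 0.9, 1.05, 8.0))
#' @export
grubbs_filter <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), !anyNA(values))
  out <- tibble::tibble(value = as.double(values), outlier = FALSE,
                        step = NA_integer_)
  active <- rep(TRUE, nrow(out))
  step <- 0L
  repeat {
    x <- out$value[active]
    n <- length(x)
    if (n < 3L) break
    s <- sd(x)
    if (s == 0) break
    g <- abs(x - mean(x)) / s
    i <- which.max(g)
    if (g[i] <= grubbs_critical(n, alpha)) break
    step <- step + 1L
    idx <- which(active)[i]
    out$outlier[idx] <- TRUE
    out$step[idx] <- step
    active[idx] <- FALSE
  }
  out
}

#' Spearman correlation between methylation and expression
#'
#' Rank correlation (with tie handling) between a CpG's methylation and
#' relative expression of a nearby gene, with a two-sided p-value. Pairs
#' with missing values are dropped; constant input is flagged rather than
#' an error.
#'
#' @param rel_expr,beta Paired numeric vectors (>= 4 complete pairs).
#' @return One-row tibble: `rho`, `p_value`, `n_used`, `status`.
#' @examples
#' methylation_expression_correlation(c(1, 2, 3, 4, 6), c(.1, .2, .3, .4, .5))
#' @export
methylation_expression_correlation <- function(rel_expr, beta) {
  stopifnot(length(rel_expr) == length(beta))
  keep <- !is.na(rel_expr) & !is.na(beta)
  x <- rel_expr[keep]
  y <- beta[keep]
  if (length(x) < 4L) {
    abort("Need at least 4 complete pairs.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n_used = length(x), status = "constant_input"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_used = length(x), status = "ok")
}

#' Test expression differences across genotype groups (eQTL pass)
#'
#' Compares relative expression across index-SNP dosage groups with either
#' a Kruskal-Wallis test (default) or a Welch t-test; with three genotype
#' groups the t-test contrasts the two extreme (homozygous) groups. Groups
#' with fewer than 2 samples are dropped; fewer than two usable groups is a
#' `"not_testable"` outcome.
#'
#' @param rel_expr Numeric vector of relative expression values.
#' @param dosage Allele-count vector in \{0, 1, 2\}, same length.
#' @param test `"kruskal_wallis"` (default) or `"t_test"`.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `n_used`,
#'   `n_groups`, `status`.
#' @examples
#' expression_by_genotype(rlnorm(30), rbinom(30, 2, 0.4))
#' @export
expression_by_genotype <- function(rel_expr, dosage,
                                   test = c("kruskal_wallis", "t_test")) {
  test <- match.arg(test)
  stopifnot(length(rel_expr) == length(dosage))
  keep <- !is.na(rel_expr) & !is.na(dosage)
  rel_expr <- rel_expr[keep]
  dosage <- dosage[keep]
  sizes <- table(dosage)
  eligible <- as.double(names(sizes)[sizes >= 2])
  keep <- dosage %in% eligible
  rel_expr <- rel_expr[keep]
  dosage <- dosage[keep]
  if (length(eligible) < 2L) {
    return(tibble::tibble(test = test, statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, n_used = length(rel_expr),
                          n_groups = length(eligible),
                          status = "not_testable"))
  }
  if (test == "kruskal_wallis") {
    kw <- kruskal.test(rel_expr, factor(dosage))
    tibble::tibble(test = test, statistic = unname(kw$statistic),
                   df = as.double(kw$parameter), p_value = kw$p.value,
                   n_used = length(rel_expr),
                   n_groups = length(eligible), status = "ok")
  } else {
    lo <- min(eligible)
    hi <- max(eligible)
    tt <- t.test(rel_expr[dosage == lo], rel_expr[dosage == hi])
    tibble::tibble(test = test, statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_used = sum(dosage %in% c(lo, hi)),
                   n_groups = length(eligible), status = "ok")
  }
}
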