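#' Quality-control PCR duplicate pyrosequencing measurements
#'
#' Pyrosequencing percent-methylation is measured in PCR duplicates; a
#' sample is excluded at a CpG when its two replicates differ by more than
#' `max_diff` percentage points (the rule is strict: a difference of exactly
#' `max_diff` is retained). The replicate mean is reported for every pair;
#' only `qc_pass` pairs enter downstream tests.
#'
#' @param data Tibble with numeric columns `rep1` and `rep2`, percent
#'   methylation in \[0, 100\].
#' @param max_diff Exclusion threshold in percentage points (default 5).
#' @return `data` with added columns `mean_pct` and `qc_pass`.
#' @examples
#' qc_duplicates(tibble::tibble(rep1 = c(50, 50, 48), rep2 = c(54, 56, 53)))
#' @export
qc_duplicates <- function(data, max_diff = 5) {
  stopifnot(is.data.frame(data), all(c("rep1", "rep2") %in% names(data)))
  bad <- which(data$rep1 < 0 | data$rep1 > 100 |
                 data$rep2 < 0 | data$rep2 > 100 |
                 is.na(data$rep1) | is.na(data$rep2))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid percent-methylation measurement (outside [0, 100]) in row(s): %s",
      paste(head(bad, 10), collapse = ", ")))
  }
  dplyr::mutate(tibble::as_tibble(data),
                mean_pct = (.data$rep1 + .data$rep2) / 2,
                qc_pass = abs(.data$rep1 - .data$rep2) <= max_diff)
}

#' Kruskal-Wallis test of percent methylation across genotype groups
#'
#' Rank-based comparison of methylation across the dosage groups 0/1/2,
#' with tie correction, p-value from the chi-squared approximation with
#' (groups - 1) degrees of freedom. Groups with fewer than `min_group_n`
#' samples are dropped; fewer than two usable groups gives a
#' `"not_testable"` outcome.
#'
#' @param values Numeric vector (percent methylation of QC-passing samples).
#' @param dosage Allele-count vector in \{0, 1, 2\}, same length.
#' @param min_group_n Minimum samples per genotype group (default 2).
#' @return One-row tibble: `statistic` (H), `df`, `p_raw`, `n_used`,
#'   `n_groups`, `status`, and a `group_means` list-column
#'   (`dosage`, `n`, `mean`).
#' @examples
#' kruskal_wallis_by_genotype(c(70, 72, 66, 64, 59, 61),
#'                            c(0, 0, 1, 1, 2, 2))
#' @export
kruskal_wallis_by_genotype <- function(values, dosage, min_group_n = 2) {
  stopifnot(length(values) == length(dosage))
  keep <- !is.na(values) & !is.na(dosage)
  values <- values[keep]
  dosage <- dosage[keep]
  sizes <- table(dosage)
  eligible <- names(sizes)[sizes >= min_group_n]
  keep <- as.character(dosage) %in% eligible
  values <- values[keep]
  dosage <- dosage[keep]
  grp_sizes <- table(dosage)
  grp_means <- as.double(tapply(values, dosage, mean))
  means <- tibble::tibble(
    dosage = as.double(names(grp_sizes)),
    n = as.integer(grp_sizes),
    mean = grp_means
  )
  if (length(eligible) < 2L) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p_raw = NA_real_, n_used = length(values),
                          n_groups = length(eligible),
                          status = "not_testable",
                          group_means = list(means)))
  }
  kw <- kruskal.test(values, factor(dosage))
  tibble::tibble(statistic = unname(kw$statistic),
                 df = as.integer(kw$parameter), p_raw = kw$p.value,
                 n_used = length(values), n_groups = length(eligible),
                 status = "ok", group_means = list(means))
}

#' Bonferroni correction
#'
#' Family-wise error-rate correction used in the replication stage:
#' `min(1, k * p)` where `k` is the number of CpGs tested in the batch.
#'
#' @param p Raw p-value(s).
#' @param k Number of tests in the family (>= 1).
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni_adjust(0.004, 3)
#' @export
bonferroni_adjust <- function(p, k) {
  if (any(k < 1)) abort("`k` must be >= 1.")
  pmin(1, k * p)
}

#' Direction consistency between discovery and replication
#'
#' A replication hit only counts when the genotype-group means move in the
#' same direction as the discovery regression slope (expressed per risk
#' allele). The trend is read off the two extreme genotype groups; a
#' difference within `tolerance` percentage points is called `"flat"` and
#' never matches.
#'
#' @param group_means Tibble with columns `dosage` (risk-allele dosage) and
#'   `mean` (percent methylation), as in the `group_means` column of
#'   [kruskal_wallis_by_genotype()] output when dosages are risk-oriented.
#' @param discovery_direction `"lower"` or `"higher"` (methylation vs risk
#'   allele from the discovery scan).
#' @param tolerance Flatness tolerance in percentage points (default 0.5).
#' @return One-row tibble: `direction` (`"lower"`, `"higher"` or `"flat"`),
#'   `matches` (logical).
#' @examples
#' gm <- tibble::tibble(dosage = 0:2, mean = c(70, 65, 60))
#' direction_consistency(gm, "lower")
#' @export
direction_consistency <- function(group_means, discovery_direction,
                                  tolerance = 0.5) {
  stopifnot(is.data.frame(group_means),
            all(c("dosage", "mean") %in% names(group_means)))
  if (nrow(group_means) < 2L) {
    abort("Need means for at least two genotype groups.")
  }
  if (!discovery_direction %in% c("lower", "higher")) {
    abort("`discovery_direction` must be \"lower\" or \"higher\".")
  }
  gm <- group_means[order(group_means$dosage), ]
  diff <- gm$mean[nrow(gm)] - gm$mean[1]
  direction <- if (abs(diff) <= tolerance) "flat"
               else if (diff < 0) "lower" else "higher"
  tibble::tibble(direction = direction,
                 matches = direction == discovery_direction)
}

#' Fraction of loci that replicated
#'
#' Percentage of tested loci whose meQTL replicated, e.g. 3 of 16 loci is
#' 18.75%.
#'
#' @param n_replicated,n_loci Counts.
#' @return Percentage (0-100).
#' @export
replication_frequency <- function(n_replicated, n_loci) {
  stopifnot(n_loci >= 1, n_replicated >= 0, n_replicated <= n_loci)
  100 * n_replicated / n_loci
}

#' Replicate discovery meQTLs on pyrosequencing data
#'
#' The replication-stage pipeline: per-CpG duplicate QC (> `max_diff`
#' percentage-point disagreement excluded), Kruskal-Wallis test of mean
#' percent methylation across risk-allele dosage groups, Bonferroni
#' correction over the `k` CpGs in the batch, and a direction-consistency
#' check against the discovery result. A CpG replicates when its adjusted
#' p is below `alpha` and its genotype trend matches the discovery
#' direction. Per locus, NOF samples can be excluded (used in the study for
#' loci where methylation differed between OA and NOF patients).
#'
#' @param pyro Tibble of duplicate measurements: `sample_id`, `cpg_id`,
#'   `rep1`, `rep2` (percent scale).
#' @param dosages Tibble of minor-allele dosages: `sample_id` plus one
#'   column per SNP.
#' @param cpg_map Tibble mapping each tested CpG to its locus: `cpg_id`,
#'   `snp_id`, `discovery_direction` (`"lower"`/`"higher"` vs risk allele),
#'   and optionally `exclude_nof` (logical, default FALSE).
#' @param loci Locus table supplying allele orientation (`snp_id`,
#'   `minor_allele`, `risk_allele`); default [oa_loci()].
#' @param samples Optional sample sheet (`sample_id`, `status`) needed when
#'   any `exclude_nof` is TRUE.
#' @param k Bonferroni family size; defaults to the number of distinct CpGs
#'   in `pyro`.
#' @param max_diff Duplicate QC threshold in percentage points (default 5).
#' @param tolerance Direction flatness tolerance (default 0.5).
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return An object of class `meqtl_replication`: list with `results`
#'   (per-CpG tibble: `cpg_id`, `snp_id`, `n_used`, `n_groups`,
#'   `statistic`, `p_raw`, `p_adj`, `direction`, `direction_match`,
#'   `replicated`, `status`, `group_means` list-column), `qc_log`
#'   (excluded measurements) and `params`.
#' @examples
#' cfg <- sim_config(seed = 4)
#' rep <- simulate_replication(cfg, seed = 5)
#' cpgs <- dplyr::mutate(
#'   dplyr::select(oa_meqtl_cpgs(), cpg_id = probe_id, snp_id),
#'   discovery_direction = "lower")
#' replicate_meqtls(rep$pyro, rep$dosages, cpgs)
#' @export
replicate_meqtls <- function(pyro, dosages, cpg_map, loci = oa_loci(),
                             samples = NULL, k = NULL, max_diff = 5,
                             tolerance = 0.5, alpha = 0.05) {
  stopifnot(is.data.frame(pyro),
            all(c("sample_id", "cpg_id", "rep1", "rep2") %in% names(pyro)))
  stopifnot(all(c("cpg_id", "snp_id", "discovery_direction") %in%
                  names(cpg_map)))
  if (!"exclude_nof" %in% names(cpg_map)) cpg_map$exclude_nof <- FALSE
  if (any(cpg_map$exclude_nof) && is.null(samples)) {
    abort("`samples` sheet required when `exclude_nof` is set.")
  }
  k <- k %||% dplyr::n_distinct(pyro$cpg_id)

  qc <- qc_duplicates(pyro, max_diff = max_diff)
  qc_log <- dplyr::filter(qc, !.data$qc_pass)
  qc <- dplyr::filter(qc, .data$qc_pass)

  results <- purrr::pmap(
    list(cpg_map$cpg_id, cpg_map$snp_id, cpg_map$discovery_direction,
         cpg_map$exclude_nof),
    function(cpg, snp, disc_dir, excl_nof) {
      dat <- dplyr::filter(qc, .data$cpg_id == cpg)
      if (excl_nof) {
        nof_ids <- samples$sample_id[samples$status == "NOF"]
        dat <- dplyr::filter(dat, !.data$sample_id %in% nof_ids)
      }
      if (!snp %in% names(dosages)) {
        abort(sprintf("SNP %s not found in replication dosages.", snp))
      }
      dos <- dosages[[snp]][match(dat$sample_id, dosages$sample_id)]
      lrow <- loci[loci$snp_id == snp, ]
      risk_dos <- if (nrow(lrow) == 1L &&
                        lrow$risk_allele[[1]] != lrow$minor_allele[[1]]) {
        2 - dos
      } else dos
      kw <- kruskal_wallis_by_genotype(dat$mean_pct, risk_dos)
      dir <- if (kw$n_groups >= 2L) {
        direction_consistency(kw$group_means[[1]], disc_dir, tolerance)
      } else {
        tibble::tibble(direction = NA_character_, matches = FALSE)
      }
      p_adj <- bonferroni_adjust(kw$p_raw, k)
      tibble::tibble(
        cpg_id = cpg, snp_id = snp, n_used = kw$n_used,
        n_groups = kw$n_groups, statistic = kw$statistic,
        p_raw = kw$p_raw, p_adj = p_adj,
        direction = dir$direction, direction_match = dir$matches,
        replicated = !is.na(p_adj) & p_adj < alpha & dir$matches,
        status = kw$status, group_means = kw$group_means
      )
    }) |> purrr::list_rbind()

  structure(list(results = results, qc_log = qc_log,
                 params = list(k = k, max_diff = max_diff,
                               tolerance = tolerance, alpha = alpha)),
            class = "meqtl_replication")
}

#' @export
print.meqtl_replication <- function(x, ...) {
  cat(sprintf(
    "<meqtl_replication> %d CpGs tested (Bonferroni k = %d), %d replicated; %d duplicate pairs excluded by QC\n",
    nrow(x$results), x$params$k, sum(x$results$replicated), nrow(x$qc_log)))
  invisible(x)
}
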