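#' Run the full meQTL pipeline on a simulated or supplied cohort
#'
#' End-to-end orchestration of the analysis stages in study order:
#' discovery scan across strata, disease-group methylation comparison at
#' the discovered CpGs (driving per-locus NOF exclusion in replication,
#' as done in the study for loci where NOF methylation differed),
#' pyrosequencing replication with duplicate QC + Kruskal-Wallis +
#' Bonferroni + direction consistency, and an expression-integration pass
#' (2^-deltaCt relative expression, Grubbs outlier removal, Spearman
#' methylation-expression correlation and a genotype eQTL test) on an
#' OA-knee RNA subset.
#'
#' Replication assays exist only for CpGs with a planted effect in the
#' generator (mirroring targeted assay design); discovered CpGs without an
#' assay are dropped from replication.
#'
#' @param sim A [sim_config()] describing the cohort to simulate; ignored
#'   when `cohort` is supplied.
#' @param seed Root seed; sub-seeds for simulation stages are derived from
#'   it. Identical seed + configuration gives a bit-identical report.
#' @param cohort Optional pre-built `meqtl_cohort` (e.g. from
#'   [read_cohort()]); when supplied only the analysis stages run on it,
#'   plus simulated replication/expression stages.
#' @param passes Analysis passes for the scan (see [scan_strata()]).
#' @param alpha Adjusted-p significance threshold (0.05).
#' @param default_span,step Window parameters in bp.
#' @param k Bonferroni family size for replication (default: number of
#'   CpGs with assays).
#' @param tolerance Replication direction flatness tolerance (percentage
#'   points).
#' @param n_expression Number of OA knee samples with RNA (default 29).
#' @param out_dir Optional directory; when set, the result tables are
#'   written there as TSV.
#' @return An object of class `meqtl_report`: list with `scan`
#'   (`meqtl_scan`), `group_comparison`, `replication`
#'   (`meqtl_replication` or NULL), `expression`, `summary` (per-locus
#'   overview), and `metadata` (seed, package version, config hash).
#' @examples
#' report <- run_pipeline(sim_config(), seed = 1, passes = c("all", "OA"))
#' report$summary
#' @export
run_pipeline <- function(sim = sim_config(), seed = 1, cohort = NULL,
                         passes = default_passes(), alpha = 0.05,
                         default_span = 1e6, step = 5e5, k = NULL,
                         tolerance = 0.5, n_expression = 29,
                         out_dir = NULL) {
  set.seed(seed)
  sub_seed <- sample.int(.Machine$integer.max, 3)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(sim, seed = sub_seed[1])
  }

  scan <- scan_strata(cohort, passes = passes, alpha = alpha,
                      default_span = default_span, step = step)
  hits_all <- dplyr::filter(scan$results,
                            .data$stratum_label == passes[1],
                            .data$significant)

  # disease-group comparison at each discovered CpG; loci where the groups
  # differ have their NOF samples excluded from replication
  group_comparison <- purrr::map(seq_len(nrow(hits_all)), function(i) {
    probe <- hits_all$probe_id[i]
    d <- tibble::tibble(
      beta = cohort$betas[[probe]],
      group = dplyr::case_when(
        cohort$samples$status == "NOF" ~ "NOF",
        cohort$samples$joint == "knee" ~ "OA_knee",
        TRUE ~ "OA_hip"))
    cmp <- group_methylation_comparison(d, .data$beta, .data$group)
    dplyr::bind_cols(tibble::tibble(locus_id = hits_all$locus_id[i],
                                    probe_id = probe), cmp)
  }) |> purrr::list_rbind()
  nof_differs <- unique(group_comparison$locus_id[
    !is.na(group_comparison$p_value) & group_comparison$p_value < alpha])

  # replication on CpGs that both hit in discovery and carry an assay
  replication <- NULL
  rep_data <- simulate_replication(if (!is.null(cohort$config)) {
    cohort$config
  } else sim, cohort = if (!is.null(cohort$truth)) cohort else NULL,
  seed = sub_seed[2])
  cpg_map <- hits_all |>
    dplyr::filter(.data$probe_id %in% unique(rep_data$pyro$cpg_id)) |>
    dplyr::transmute(
      cpg_id = .data$probe_id, snp_id = .data$snp_id,
      discovery_direction = .data$direction_vs_risk,
      exclude_nof = .data$locus_id %in% nof_differs) |>
    dplyr::filter(.data$discovery_direction %in% c("lower", "higher"))
  if (nrow(cpg_map) > 0L) {
    replication <- replicate_meqtls(
      rep_data$pyro, rep_data$dosages, cpg_map, loci = cohort$loci,
      samples = rep_data$samples, k = k, tolerance = tolerance,
      alpha = alpha)
  }

  # expression integration on an OA knee RNA subset: one target gene per
  # locus with a discovery hit, linked to its most significant CpG
  expression <- NULL
  if (nrow(hits_all) > 0L && n_expression >= 4) {
    set.seed(sub_seed[3])
    knee_ids <- cohort$samples$sample_id[cohort$samples$status == "OA" &
                                           cohort$samples$joint == "knee"]
    rna_ids <- head(knee_ids, n_expression)
    top <- hits_all |>
      dplyr::group_by(.data$locus_id) |>
      dplyr::slice_min(.data$p_adj, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    cfg <- cohort$config %||% sim
    expression <- purrr::map(seq_len(nrow(top)), function(i) {
      probe <- top$probe_id[i]
      snp <- top$snp_id[i]
      beta <- cohort$betas[[probe]][match(rna_ids,
                                          cohort$betas$sample_id)]
      ct <- simulate_expression(
        beta, link_slope = cfg$expression_link_slope,
        noise_sd = cfg$expression_noise_sd,
        gene = top$locus_id[i], sample_id = rna_ids)
      expr <- relative_expression(ct)
      gr <- grubbs_filter(expr$rel_expr)
      keep <- !gr$outlier
      dos <- cohort$dosages[[snp]][match(rna_ids,
                                         cohort$dosages$sample_id)]
      corr <- methylation_expression_correlation(expr$rel_expr[keep],
                                                 beta[keep])
      eqtl <- expression_by_genotype(expr$rel_expr[keep], dos[keep])
      tibble::tibble(
        locus_id = top$locus_id[i], gene = top$locus_id[i],
        probe_id = probe, snp_id = snp, n_rna = sum(keep),
        n_outliers = sum(gr$outlier), spearman_rho = corr$rho,
        spearman_p = corr$p_value, eqtl_test = eqtl$test,
        eqtl_p = eqtl$p_value)
    }) |> purrr::list_rbind()
  }

  scan_summary <- summarise_scan(scan)
  rep_by_locus <- if (!is.null(replication)) {
    replication$results |>
      dplyr::left_join(dplyr::select(cohort$loci, "locus_id", "snp_id"),
                       by = "snp_id") |>
      dplyr::group_by(.data$locus_id) |>
      dplyr::summarise(replicated = any(.data$replicated),
                       .groups = "drop")
  } else {
    tibble::tibble(locus_id = character(), replicated = logical())
  }
  summary <- scan_summary |>
    dplyr::filter(.data$stratum_label == passes[1]) |>
    dplyr::left_join(rep_by_locus, by = "locus_id")

  metadata <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("meqtlscan")),
    passes = passes, alpha = alpha,
    config_hash = rlang::hash(list(sim_fields = unclass(sim), seed = seed,
                                   passes = passes, alpha = alpha,
                                   default_span = default_span,
                                   step = step, tolerance = tolerance,
                                   n_expression = n_expression)))

  report <- structure(
    list(scan = scan, group_comparison = group_comparison,
         replication = replication, expression = expression,
         summary = summary, metadata = metadata),
    class = "meqtl_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(scan$results, file.path(out_dir, "scan_results.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "locus_summary.tsv"))
    if (!is.null(replication)) {
      readr::write_tsv(
        dplyr::select(replication$results, -"group_means"),
        file.path(out_dir, "replication_results.tsv"))
      readr::write_tsv(replication$qc_log,
                       file.path(out_dir, "replication_qc_log.tsv"))
    }
    if (!is.null(expression)) {
      readr::write_tsv(expression, file.path(out_dir,
                                             "expression_results.tsv"))
    }
  }
  report
}

#' @export
print.meqtl_report <- function(x, ...) {
  cat("<meqtl_report>\n")
  cat(sprintf("  seed %s | package %s | config %s\n", x$metadata$seed,
              x$metadata$package_version,
              substr(x$metadata$config_hash, 1, 8)))
  sig <- dplyr::filter(x$summary, .data$n_significant > 0)
  cat(sprintf("  discovery: %d of %d loci with significant CpGs (adj. p < %s)\n",
              nrow(sig), nrow(x$summary), format(x$metadata$alpha)))
  for (i in seq_len(nrow(sig))) {
    cat(sprintf(
      "    %-8s %-11s %d/%d CpGs, min adj. p = %.3g, %s methylation with risk allele, max var expl %.1f%%%s\n",
      sig$locus_id[i], sig$snp_id[i], sig$n_significant[i], sig$m[i],
      sig$min_p_adj[i], sig$direction[i], sig$max_pct_var[i],
      ifelse(isTRUE(sig$replicated[i]), ", replicated",
             ifelse(isFALSE(sig$replicated[i]), ", not replicated", ""))))
  }
  if (!is.null(x$replication)) {
    n_rep_loci <- sum(x$summary$replicated, na.rm = TRUE)
    cat(sprintf("  replication: %d of %d tested CpGs replicated; %d of %d loci (%.1f%% of panel)\n",
                sum(x$replication$results$replicated),
                nrow(x$replication$results), n_rep_loci,
                nrow(x$summary),
                replication_frequency(n_rep_loci, nrow(x$summary))))
  }
  if (!is.null(x$expression)) {
    cat(sprintf("  expression: %d gene-CpG pairs tested, %d with Spearman p < %s\n",
                nrow(x$expression),
                sum(x$expression$spearman_p < x$metadata$alpha,
                    na.rm = TRUE), format(x$metadata$alpha)))
  }
  invisible(x)
}
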