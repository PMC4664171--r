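#' Region association plot for one locus
#'
#' -log10 adjusted p against probe position across a locus window, with
#' the index SNP (bold dashed line), LD-block bounds (dotted lines) and
#' the significance threshold marked — the standard way a cis-meQTL region
#' is displayed.
#'
#' @param object A `meqtl_scan` object.
#' @param locus_id Locus to plot (default: first locus).
#' @param pass Analysis pass (default `"all"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1))
#' scan <- scan_strata(cohort, passes = "all")
#' autoplot(scan, locus_id = "SUPT3H")
#' @exportS3Method ggplot2::autoplot
autoplot.meqtl_scan <- function(object, locus_id = NULL, pass = "all",
                                ...) {
  locus_id <- locus_id %||% object$loci$locus_id[1]
  l <- object$loci[object$loci$locus_id == locus_id, ]
  d <- dplyr::filter(object$results, .data$locus_id == !!locus_id,
                     .data$stratum_label == pass)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position / 1e6,
                                  y = -log10(.data$p_adj))) +
    ggplot2::geom_point(shape = 1, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = l$position / 1e6, linetype = "dashed",
                        linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(l$ld_start, l$ld_end) / 1e6,
                        linetype = "dotted") +
    ggplot2::labs(
      x = sprintf("Position on chromosome %s (Mb)", l$chromosome),
      y = expression(-log[10] ~ "adjusted" ~ italic(P)),
      title = sprintf("%s (%s), %s pass", locus_id, l$snp_id, pass)) +
    ggplot2::theme_classic()
}

#' Methylation by genotype at one CpG
#'
#' Per-sample beta-values stratified by index-SNP genotype with the group
#' mean marked, the display used for each discovered meQTL.
#'
#' @param cohort A `meqtl_cohort`.
#' @param snp_id Index SNP (must be a dosage column).
#' @param probe_id CpG probe (must be a beta column).
#' @param sample_ids Optional stratum restriction.
#' @return A ggplot object.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1))
#' plot_genotype_methylation(cohort, "rs3204689", "cg12031962")
#' @export
plot_genotype_methylation <- function(cohort, snp_id, probe_id,
                                      sample_ids = NULL) {
  ids <- sample_ids %||% cohort$samples$sample_id
  l <- cohort$loci[cohort$loci$snp_id == snp_id, ]
  dos <- cohort$dosages[[snp_id]][match(ids, cohort$dosages$sample_id)]
  geno <- genotype_labels(dos, l$major_allele[1], l$minor_allele[1])
  d <- tibble::tibble(
    genotype = geno,
    beta = cohort$betas[[probe_id]][match(ids, cohort$betas$sample_id)])
  d <- dplyr::filter(d, !is.na(.data$genotype), !is.na(.data$beta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$beta)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, colour = "red") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("%s genotype", snp_id),
                  y = sprintf("%s methylation (beta-value)", probe_id)) +
    ggplot2::theme_classic()
}

genotype_labels <- function(dosage, major, minor) {
  lab <- c(paste0(major, major), paste0(major, minor), paste0(minor, minor))
  factor(lab[dosage + 1], levels = lab)
}

#' Replication genotype-group means per CpG
#'
#' Group mean percent methylation along risk-allele dosage for each
#' replication CpG, annotated with the Bonferroni-adjusted p-value.
#'
#' @param object A `meqtl_replication` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meqtl_replication <- function(object, ...) {
  d <- object$results |>
    dplyr::mutate(label = sprintf("%s\nadj. p = %.3g", .data$cpg_id,
                                  .data$p_adj)) |>
    dplyr::select("label", "group_means") |>
    tidyr::unnest("group_means")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$dosage),
                                  y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), linetype = "dotted") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "Risk-allele dosage",
                  y = "Mean methylation (%)") +
    ggplot2::theme_classic()
}

#' Methylation-expression scatter plot
#'
#' Relative expression (2^-deltaCt) against CpG methylation with the
#' Spearman rank correlation in the subtitle.
#'
#' @param data Tibble of paired observations.
#' @param beta,rel_expr Columns of `data` (tidy-eval).
#' @return A ggplot object.
#' @export
plot_methylation_expression <- function(data, beta, rel_expr) {
  b <- dplyr::pull(data, {{ beta }})
  e <- dplyr::pull(data, {{ rel_expr }})
  ct <- methylation_expression_correlation(e, b)
  ggplot2::ggplot(tibble::tibble(beta = b, expr = e),
                  ggplot2::aes(x = .data$beta, y = .data$expr)) +
    ggplot2::geom_point(shape = 1, na.rm = TRUE) +
    ggplot2::labs(x = "Methylation (beta-value)",
                  y = expression(2^{-Delta * Ct} ~ "relative expression"),
                  subtitle = sprintf("Spearman r = %.2f, p = %.3g",
                                     ct$rho, ct$p_value)) +
    ggplot2::theme_classic()
}
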