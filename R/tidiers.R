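#' Tidy a stratified meQTL scan
#'
#' Returns the per locus x probe x pass result table (one regression per
#' row) in broom convention.
#'
#' @param x A `meqtl_scan` object.
#' @param ... Unused.
#' @return A tibble; see [scan_locus()] for columns.
#' @exportS3Method broom::tidy
tidy.meqtl_scan <- function(x, ...) {
  x$results
}

#' One-row summary of a stratified meQTL scan
#'
#' @param x A `meqtl_scan` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_loci`, `n_passes`, `n_tests`,
#'   `n_significant`, `n_significant_loci` (loci with a hit in any pass),
#'   `alpha`.
#' @exportS3Method broom::glance
glance.meqtl_scan <- function(x, ...) {
  sig <- dplyr::filter(x$results, .data$significant)
  tibble::tibble(
    n_loci = nrow(x$loci), n_passes = length(x$passes),
    n_tests = nrow(x$results), n_significant = nrow(sig),
    n_significant_loci = dplyr::n_distinct(sig$locus_id),
    alpha = x$params$alpha)
}

#' Tidy a replication analysis
#'
#' @param x A `meqtl_replication` object.
#' @param ... Unused.
#' @return The per-CpG results tibble (without the nested group means).
#' @exportS3Method broom::tidy
tidy.meqtl_replication <- function(x, ...) {
  dplyr::select(x$results, -"group_means")
}

#' One-row summary of a replication analysis
#'
#' @param x A `meqtl_replication` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_cpgs`, `k`, `n_replicated`,
#'   `n_direction_match`, `n_qc_excluded`, `alpha`.
#' @exportS3Method broom::glance
glance.meqtl_replication <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x$results), k = x$params$k,
    n_replicated = sum(x$results$replicated),
    n_direction_match = sum(x$results$direction_match, na.rm = TRUE),
    n_qc_excluded = nrow(x$qc_log), alpha = x$params$alpha)
}
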