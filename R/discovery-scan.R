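# Vectorised ordinary least squares of a response matrix on one predictor.
# Missing values are handled by pairwise deletion per column. Returns one row
# per column of `y`. This closed-form path is the workhorse of the region
# scans (hundreds of probes per locus), so it avoids lm() overhead.
ols_matrix <- function(y, x) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  x <- as.double(x)
  stopifnot(nrow(y) == length(x))
  keep <- !is.na(x)
  y <- y[keep, , drop = FALSE]
  x <- x[keep]

  obs <- !is.na(y)
  y0 <- y
  y0[!obs] <- 0
  n <- colSums(obs)
  sx <- as.double(crossprod(obs, x))
  sxx <- as.double(crossprod(obs, x^2))
  sy <- colSums(y0)
  syy <- colSums(y0^2)
  sxy <- as.double(crossprod(y0, x))

  sxx_c <- sxx - sx^2 / n
  syy_c <- pmax(0, syy - sy^2 / n)
  sxy_c <- sxy - sx * sy / n

  eps <- 1e-12
  status <- rep("ok", ncol(y))
  status[n < 3] <- "insufficient_data"
  status[n >= 3 & sxx_c <= eps * pmax(1, sxx)] <- "monomorphic"
  ok <- status == "ok"

  slope <- intercept <- p_raw <- r2 <- rep(NA_real_, ncol(y))
  slope[ok] <- sxy_c[ok] / sxx_c[ok]
  intercept[ok] <- (sy[ok] - slope[ok] * sx[ok]) / n[ok]
  denom <- sxx_c * syy_c
  r2[ok] <- ifelse(denom[ok] > eps^2, sxy_c[ok]^2 / denom[ok], 0)
  sse <- pmax(0, syy_c - slope * sxy_c)
  sigma2 <- sse / (n - 2)
  se <- sqrt(sigma2 / sxx_c)
  tval <- slope / se
  p_raw[ok] <- 2 * pt(-abs(tval[ok]), df = n[ok] - 2)
  # zero residual spread: constant response carries no evidence against the
  # null; an exact fit with spread is overwhelming evidence
  degenerate <- ok & sse <= eps & syy_c <= eps
  p_raw[degenerate] <- 1
  slope[degenerate] <- 0
  exactfit <- ok & sse <= eps & syy_c > eps
  p_raw[exactfit] <- 0

  tibble::tibble(
    probe_id = colnames(y) %||% as.character(seq_len(ncol(y))),
    n_used = as.integer(n), slope = slope, intercept = intercept,
    p_raw = p_raw, r_squared = r2, status = status
  )
}

#' Regress methylation on minor-allele dosage
#'
#' The core meQTL statistic: ordinary least squares of a CpG's methylation
#' beta-value on the count of minor alleles (0, 1 or 2) at the index SNP,
#' with a two-sided t-test of zero slope. Missing values in either vector
#' are dropped pairwise. Degenerate inputs do not raise errors but are
#' flagged via `status`, so a multi-locus scan always completes:
#' `"monomorphic"` when all (remaining) dosages are identical,
#' `"insufficient_data"` with fewer than 3 complete pairs.
#'
#' @param beta Numeric vector of methylation beta-values in \[0, 1\]
#'   (`NA` allowed).
#' @param dosage Numeric vector of minor-allele counts in \{0, 1, 2\}
#'   (`NA` allowed), same length as `beta`.
#' @return A one-row tibble: `n_used`, `slope` (beta units per minor
#'   allele), `intercept`, `p_raw`, `r_squared`, `status`.
#' @examples
#' dosage_regression(c(0.20, 0.31, 0.39, 0.21, 0.29, 0.41),
#'                   c(0, 1, 2, 0, 1, 2))
#' @export
dosage_regression <- function(beta, dosage) {
  if (length(beta) != length(dosage)) {
    abort("`beta` and `dosage` must have the same length.")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) > 0 && !all(bad %in% c(0, 1, 2))) {
    abort("`dosage` values must be 0, 1 or 2 (minor-allele counts).")
  }
  out <- ols_matrix(matrix(beta, ncol = 1), dosage)
  out$probe_id <- NULL
  out
}

#' Benjamini-Hochberg adjustment over a region's probe family
#'
#' Step-up false-discovery-rate correction of the per-probe regression
#' p-values, with the family size `m` fixed to the number of CpG probes in
#' the tested region (every region probe is tested, so `m` normally equals
#' `length(p)`; it is passed explicitly because the region probe count is
#' the documented multiplicity denominator). Input order is preserved;
#' `NA` p-values stay `NA` and do not consume part of the family.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size; must be at least the number of non-missing
#'   p-values.
#' @return Adjusted p-values, same length/order as `p`, capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))      # all 0.03
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  n_obs <- sum(!is.na(p))
  if (m < n_obs) {
    abort(sprintf("`m` (%d) is smaller than the number of p-values (%d).",
                  m, n_obs))
  }
  out <- rep(NA_real_, length(p))
  out[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH", n = m)
  out
}

risk_sign <- function(risk_allele, minor_allele) {
  ifelse(risk_allele == minor_allele, 1, -1)
}

direction_label <- function(slope, risk_allele, minor_allele, tol = 0) {
  rs <- slope * risk_sign(risk_allele, minor_allele)
  dplyr::case_when(
    is.na(rs) ~ NA_character_,
    abs(rs) <= tol ~ "flat",
    rs < 0 ~ "lower",
    TRUE ~ "higher"
  )
}

#' Scan one locus region for genotype-methylation association
#'
#' Runs the dosage regression for every CpG probe in the locus analysis
#' window, applies region-wise Benjamini-Hochberg correction over the full
#' probe family, and annotates each probe with significance (adjusted
#' p < `alpha`), the direction of the methylation effect re-expressed per
#' copy of the OA risk allele (risk dosage = minor dosage when the risk
#' allele is minor, else 2 - dosage), the percent of methylation variance
#' explained by genotype, and its distance from the index SNP.
#'
#' A stratum that selects no samples returns zero rows with a warning; a
#' stratum where the regression cannot run (too few samples, monomorphic
#' SNP) returns one flagged row per probe so the multi-locus scan completes.
#'
#' @param cohort A cohort object (see [simulate_cohort()] / [read_cohort()]):
#'   a list with `samples`, `dosages`, `betas` tibbles keyed by `sample_id`.
#' @param locus One-row tibble for the locus (a row of [build_windows()]
#'   output; must carry `locus_id`, `snp_id`, `position`, `minor_allele`,
#'   `risk_allele` and window bounds).
#' @param probes Region probes from [select_probes()]; the number of rows is
#'   the BH family size `m`.
#' @param sample_ids Optional character vector restricting the scan to a
#'   stratum; `NULL` uses every sample.
#' @param stratum_label Label stored in the output (e.g. `"all"`,
#'   `"OA_knee"`).
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return Tibble with one row per probe: `locus_id`, `snp_id`, `probe_id`,
#'   `position`, `distance_kb`, `stratum_label`, `n_used`, `slope`,
#'   `intercept`, `p_raw`, `p_adj`, `significant`, `direction_vs_risk`,
#'   `pct_var_explained`, `status`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1))
#' locus <- build_windows(dplyr::filter(cohort$loci, snp_id == "rs3204689"))
#' probes <- select_probes(cohort$manifest, locus)
#' dplyr::filter(scan_locus(cohort, locus, probes), significant)
#' @export
scan_locus <- function(cohort, locus, probes, sample_ids = NULL,
                       stratum_label = "all", alpha = 0.05) {
  stopifnot(is.data.frame(locus), nrow(locus) == 1L)
  snp <- locus$snp_id[[1]]
  if (!snp %in% names(cohort$dosages)) {
    abort(sprintf("SNP %s not found in cohort dosages.", snp))
  }
  ids <- cohort$samples$sample_id
  if (!is.null(sample_ids)) ids <- intersect(ids, sample_ids)
  if (length(ids) == 0L) {
    warn(sprintf("Stratum '%s' matches no samples for locus %s.",
                 stratum_label, locus$locus_id[[1]]))
    return(empty_scan_result())
  }
  m <- nrow(probes)
  if (m == 0L) return(empty_scan_result())

  dos <- cohort$dosages[match(ids, cohort$dosages$sample_id), snp,
                        drop = TRUE]
  beta_cols <- intersect(probes$probe_id, names(cohort$betas))
  if (length(beta_cols) < m) {
    abort(sprintf("%d region probes missing from the beta matrix.",
                  m - length(beta_cols)))
  }
  B <- as.matrix(cohort$betas[match(ids, cohort$betas$sample_id),
                              probes$probe_id, drop = FALSE])
  fits <- ols_matrix(B, dos)
  fits$p_adj <- bh_adjust(fits$p_raw, m = m)

  tibble::tibble(
    locus_id = locus$locus_id[[1]],
    snp_id = snp,
    probe_id = probes$probe_id,
    position = probes$position,
    distance_kb = distance_kb(probes$position, locus$position[[1]]),
    stratum_label = stratum_label,
    n_used = fits$n_used,
    slope = fits$slope,
    intercept = fits$intercept,
    p_raw = fits$p_raw,
    p_adj = fits$p_adj,
    significant = !is.na(fits$p_adj) & fits$p_adj < alpha,
    direction_vs_risk = direction_label(fits$slope, locus$risk_allele[[1]],
                                        locus$minor_allele[[1]]),
    pct_var_explained = 100 * fits$r_squared,
    status = fits$status
  )
}

empty_scan_result <- function() {
  tibble::tibble(
    locus_id = character(), snp_id = character(), probe_id = character(),
    position = double(), distance_kb = integer(), stratum_label = character(),
    n_used = integer(), slope = double(), intercept = double(),
    p_raw = double(), p_adj = double(), significant = logical(),
    direction_vs_risk = character(), pct_var_explained = double(),
    status = character()
  )
}

default_passes <- function() {
  c("all", "OA", "NOF", "OA_knee", "OA_hip", "male", "female")
}

pass_sample_ids <- function(samples, pass) {
  keep <- switch(
    pass,
    all = rep(TRUE, nrow(samples)),
    OA = samples$status == "OA",
    NOF = samples$status == "NOF",
    OA_knee = samples$status == "OA" & samples$joint == "knee",
    OA_hip = samples$status == "OA" & samples$joint == "hip",
    male = samples$sex == "male",
    female = samples$sex == "female",
    abort(sprintf("Unknown analysis pass '%s'.", pass))
  )
  samples$sample_id[keep]
}

#' Run the stratified multi-locus meQTL scan
#'
#' Scans every locus across a set of analysis passes, mirroring the study
#' design: all samples combined, OA only, NOF only, OA stratified by joint,
#' and stratified by sex. Each pass is Benjamini-Hochberg-corrected
#' independently, per region, over that region's full probe family.
#'
#' @param cohort Cohort object ([simulate_cohort()] / [read_cohort()]).
#' @param loci Locus table (default `cohort$loci`); windows are built if the
#'   window columns are absent.
#' @param manifest Probe manifest (default `cohort$manifest`).
#' @param passes Character vector of passes to run (see Details); default
#'   `c("all", "OA", "NOF", "OA_knee", "OA_hip", "male", "female")`.
#' @param default_span,step Window construction parameters in bp
#'   (see [build_windows()]).
#' @param alpha Adjusted-p significance threshold (0.05).
#' @param exclude_polymorphic Drop polymorphic CpGs (default TRUE).
#' @return An object of class `meqtl_scan`: a list with `results` (one row
#'   per locus x probe x pass), `loci` (with windows and the region probe
#'   count `m`), `passes`, and `params`. Use [tidy()], [glance()],
#'   [autoplot()] and [summarise_scan()] on it.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1))
#' scan <- scan_strata(cohort, passes = c("all", "OA"))
#' glance(scan)
#' @export
scan_strata <- function(cohort, loci = cohort$loci,
                        manifest = cohort$manifest,
                        passes = default_passes(),
                        default_span = 1e6, step = 5e5, alpha = 0.05,
                        exclude_polymorphic = TRUE) {
  stopifnot(is.data.frame(loci), is.data.frame(manifest))
  if (!"window_start" %in% names(loci)) {
    loci <- build_windows(loci, default_span = default_span, step = step)
  }
  probe_sets <- purrr::map(seq_len(nrow(loci)), function(i) {
    select_probes(manifest, loci[i, ], exclude_polymorphic)
  })
  loci$m <- purrr::map_int(probe_sets, nrow)

  results <- purrr::map(passes, function(pass) {
    ids <- pass_sample_ids(cohort$samples, pass)
    purrr::map(seq_len(nrow(loci)), function(i) {
      scan_locus(cohort, loci[i, ], probe_sets[[i]], sample_ids = ids,
                 stratum_label = pass, alpha = alpha)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(
    list(results = results, loci = loci, passes = passes,
         params = list(default_span = default_span, step = step,
                       alpha = alpha,
                       exclude_polymorphic = exclude_polymorphic)),
    class = "meqtl_scan"
  )
}

#' @export
print.meqtl_scan <- function(x, ...) {
  sig <- dplyr::filter(x$results, .data$significant)
  cat(sprintf("<meqtl_scan> %d loci x %d passes, %d probe tests\n",
              nrow(x$loci), length(x$passes), nrow(x$results)))
  cat(sprintf("  significant (adj. p < %s): %d probe hits at %d locus/pass\n",
              format(x$params$alpha), nrow(sig),
              nrow(dplyr::distinct(sig, .data$locus_id,
                                   .data$stratum_label))))
  invisible(x)
}

#' Per-locus summary of a stratified scan
#'
#' One row per locus and pass: probes tested (`m`), number significant,
#' smallest adjusted p, consensus direction versus the risk allele and the
#' largest percent variance explained among significant probes.
#'
#' @param scan A `meqtl_scan` object.
#' @return A tibble.
#' @export
summarise_scan <- function(scan) {
  stopifnot(inherits(scan, "meqtl_scan"))
  scan$results |>
    dplyr::group_by(.data$locus_id, .data$snp_id, .data$stratum_label) |>
    dplyr::summarise(
      m = dplyr::n(),
      n_significant = sum(.data$significant),
      min_p_adj = suppressWarnings(min(.data$p_adj, na.rm = TRUE)),
      direction = if (any(.data$significant)) {
        .data$direction_vs_risk[.data$significant][
          which.min(.data$p_adj[.data$significant])]
      } else NA_character_,
      max_pct_var = ifelse(any(.data$significant),
                           max(.data$pct_var_explained[.data$significant]),
                           NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(min_p_adj = dplyr::if_else(is.finite(.data$min_p_adj),
                                             .data$min_p_adj, NA_real_))
}

#' Compare methylation across disease groups at one CpG
#'
#' Kruskal-Wallis comparison of a CpG's methylation across patient groups
#' (typically OA-knee, OA-hip, NOF), with per-group means. Groups with fewer
#' than 2 samples are dropped with a warning; fewer than 2 usable groups
#' yields a `"not_testable"` outcome rather than an error.
#'
#' @param data Tibble with one row per sample.
#' @param value,group Columns of `data` holding the methylation value and
#'   the group label (tidy-eval).
#' @return A one-row tibble: `statistic` (Kruskal-Wallis H), `df`,
#'   `p_value`, `n_used`, `n_groups`, `status`, and a `group_means`
#'   list-column (tibble of `group`, `n`, `mean`).
#' @examples
#' d <- tibble::tibble(beta = runif(30), grp = rep(c("OA_knee", "NOF"), 15))
#' group_methylation_comparison(d, beta, grp)
#' @export
group_methylation_comparison <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0L) {
    warn(paste0("Dropping group(s) with < 2 samples: ",
                paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  means <- tibble::tibble(group = names(table(g)),
                          n = as.integer(table(g)),
                          mean = as.double(tapply(v, g, mean)))
  if (length(unique(g)) < 2L) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, n_used = length(v),
                          n_groups = length(unique(g)),
                          status = "not_testable",
                          group_means = list(means)))
  }
  kw <- kruskal.test(v, factor(g))
  tibble::tibble(statistic = unname(kw$statistic),
                 df = as.integer(kw$parameter),
                 p_value = kw$p.value, n_used = length(v),
                 n_groups = length(unique(g)), status = "ok",
                 group_means = list(means))
}

#' Percent of methylation variance explained by genotype
#'
#' 100 x R-squared of the univariate linear model of methylation on
#' minor-allele dosage — the share of inter-individual methylation
#' variability attributable to genotype at the index SNP.
#'
#' @inheritParams dosage_regression
#' @return A single percentage in \[0, 100\] (`NA` when the regression is
#'   degenerate).
#' @examples
#' variance_explained(c(0.2, 0.3, 0.4, 0.2, 0.3, 0.4), c(0, 1, 2, 0, 1, 2))
#' @export
variance_explained <- function(beta, dosage) {
  fit <- dosage_regression(beta, dosage)
  if (fit$status != "ok") return(NA_real_)
  100 * fit$r_squared
}
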