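#' Configuration for the synthetic cartilage meQTL cohort
#'
#' Bundles every parameter of the data generator. Defaults emulate the
#' study conditions: 99 discovery samples (63 OA knee, 17 OA hip, 19 NOF),
#' the 16-locus panel of [oa_loci()] with its per-region 450k probe counts,
#' additive allelic effects of -0.4 logit per risk allele planted at the
#' nine meQTL CpGs of [oa_meqtl_cpgs()] (risk allele lowers methylation, as
#' observed at all four real meQTLs), a lower-methylation NOF offset at the
#' GLT8D1 and SUPT3H planted CpGs, a male offset at three SUPT3H CpGs,
#' logit-scale Gaussian noise (sd 0.15), pyrosequencing replicate noise of
#' 2 percentage points, and a qPCR link in which target Ct increases with
#' methylation.
#'
#' Methylation is generated on the logit scale and mapped through the
#' inverse logit, so beta-values are always strictly inside (0, 1).
#'
#' @param n_oa_knee,n_oa_hip,n_nof Group sizes (63/17/19).
#' @param loci Locus table with `sim_maf` and `n_region_probes` columns
#'   (default [oa_loci()]).
#' @param planted Tibble of planted effects: `locus_id`, `probe_id`,
#'   `chromosome`, `position`, `effect_logit` (per risk allele). Default:
#'   [oa_meqtl_cpgs()] with effect -0.4.
#' @param group_offsets Tibble `probe_id`, `status`, `offset_logit`
#'   (disease-group shifts at specific probes).
#' @param sex_offsets Tibble `probe_id`, `sex`, `offset_logit`.
#' @param baseline_logit_range Range of per-probe baseline methylation on
#'   the logit scale (uniform draw).
#' @param noise_sd_logit Per-sample Gaussian noise sd, logit units (0.15).
#' @param pyro_replicate_sd Pyrosequencing replicate sd, percentage points.
#' @param expression_link_slope Target-gene Ct increase per unit of
#'   methylation beta (cycles); positive values make expression fall as
#'   methylation rises.
#' @param expression_noise_sd Target Ct noise sd (cycles).
#' @param polymorphic_rate Expected fraction of additional SNP-confounded
#'   (polymorphic) probes added per region, over and above
#'   `n_region_probes`; these are flagged and excluded by the scan, so the
#'   per-region test count m matches `n_region_probes`.
#' @param seed Optional root seed; per-stage substream seeds are derived
#'   from it so stages can be regenerated independently.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' @export
sim_config <- function(n_oa_knee = 63, n_oa_hip = 17, n_nof = 19,
                       loci = oa_loci(),
                       planted = default_planted_effects(),
                       group_offsets = default_group_offsets(),
                       sex_offsets = default_sex_offsets(),
                       baseline_logit_range = c(-1.5, 1.5),
                       noise_sd_logit = 0.15,
                       pyro_replicate_sd = 2,
                       expression_link_slope = 2,
                       expression_noise_sd = 0.5,
                       polymorphic_rate = 0.02,
                       seed = NULL) {
  stopifnot(n_oa_knee >= 0, n_oa_hip >= 0, n_nof >= 0,
            n_oa_knee + n_oa_hip + n_nof >= 3,
            noise_sd_logit >= 0, pyro_replicate_sd >= 0,
            expression_noise_sd >= 0,
            all(loci$sim_maf > 0 & loci$sim_maf < 1),
            all(loci$n_region_probes >= 1))
  if (!all(planted$locus_id %in% loci$locus_id)) {
    abort("Planted effects refer to loci absent from the locus table.")
  }
  structure(
    list(n_oa_knee = n_oa_knee, n_oa_hip = n_oa_hip, n_nof = n_nof,
         loci = loci, planted = planted, group_offsets = group_offsets,
         sex_offsets = sex_offsets,
         baseline_logit_range = baseline_logit_range,
         noise_sd_logit = noise_sd_logit,
         pyro_replicate_sd = pyro_replicate_sd,
         expression_link_slope = expression_link_slope,
         expression_noise_sd = expression_noise_sd,
         polymorphic_rate = polymorphic_rate, seed = seed),
    class = "sim_config")
}

#' @rdname sim_config
#' @param effect_logit Planted additive effect per risk allele, logit units.
#' @export
default_planted_effects <- function(effect_logit = -0.4) {
  dplyr::mutate(
    dplyr::select(oa_meqtl_cpgs(), "locus_id", "probe_id", "chromosome",
                  "position"),
    effect_logit = effect_logit)
}

#' @rdname sim_config
#' @export
default_group_offsets <- function() {
  cpgs <- oa_meqtl_cpgs()
  tibble::tibble(
    probe_id = cpgs$probe_id[cpgs$locus_id %in% c("GLT8D1", "SUPT3H")],
    status = "NOF", offset_logit = -0.3)
}

#' @rdname sim_config
#' @export
default_sex_offsets <- function() {
  tibble::tibble(
    probe_id = c("cg13979708", "cg20913747", "cg18551225"),
    sex = "male", offset_logit = -0.2)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Independent minor-allele counts with P(0, 1, 2) =
#' ((1-maf)^2, 2 maf (1-maf), maf^2).
#'
#' @param n Number of samples.
#' @param maf Minor-allele frequency, strictly in (0, 1).
#' @param seed Optional seed.
#' @return Integer vector in \{0, 1, 2\}.
#' @examples
#' table(simulate_genotypes(1000, 0.3, seed = 1))
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(maf) || maf <= 0 || maf >= 1) {
    abort("`maf` must lie strictly in (0, 1).")
  }
  rbinom(n, 2L, maf)
}

inv_logit_clamped <- function(x) {
  pmin(1 - 1e-12, pmax(1e-12, plogis(x)))
}

#' Simulate methylation beta-values on the logit scale
#'
#' `beta = inverse-logit(baseline + effect * dosage + offsets + noise)`,
#' with Gaussian noise on the logit scale so values never leave (0, 1).
#' `dosage` is conventionally the risk-allele dosage when `effect_logit`
#' is a per-risk-allele effect.
#'
#' @param dosage Numeric allele-count vector.
#' @param baseline_logit Baseline methylation, logit units.
#' @param effect_logit Additive effect per allele, logit units.
#' @param offsets Per-sample additive offsets (scalar or vector), logit
#'   units.
#' @param noise_sd Noise sd, logit units (>= 0).
#' @param seed Optional seed.
#' @return Numeric vector of beta-values strictly inside (0, 1).
#' @examples
#' simulate_methylation(c(0, 1, 2), 0, -0.4, noise_sd = 0, seed = 1)
#' @export
simulate_methylation <- function(dosage, baseline_logit, effect_logit = 0,
                                 offsets = 0, noise_sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  n <- length(dosage)
  lin <- baseline_logit + effect_logit * dosage + offsets +
    rnorm(n, 0, noise_sd)
  inv_logit_clamped(lin)
}

#' Simulate duplicate pyrosequencing measurements
#'
#' Two independent percent-methylation reads around `100 * beta_true`,
#' truncated to \[0, 100\] — the input expected by the duplicate QC rule.
#'
#' @param beta_true True methylation fractions in \[0, 1\].
#' @param replicate_sd Replicate noise sd in percentage points.
#' @param seed Optional seed.
#' @return Tibble with columns `rep1`, `rep2`.
#' @examples
#' simulate_pyro(c(0.2, 0.8), replicate_sd = 2, seed = 1)
#' @export
simulate_pyro <- function(beta_true, replicate_sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (replicate_sd < 0) abort("`replicate_sd` must be >= 0.")
  n <- length(beta_true)
  clamp <- function(x) pmin(100, pmax(0, x))
  tibble::tibble(
    rep1 = clamp(100 * beta_true + rnorm(n, 0, replicate_sd)),
    rep2 = clamp(100 * beta_true + rnorm(n, 0, replicate_sd)))
}

#' Simulate a qPCR Ct table linked to a predictor
#'
#' Housekeeping Cts are drawn around fixed means (18S, GAPDH, HPRT1 roles)
#' and the target Ct is `baseline_ct + link_slope * predictor + noise`, so
#' the resulting 2^-deltaCt relative expression carries the planted
#' association (a positive `link_slope` on methylation yields a negative
#' methylation-expression correlation).
#'
#' @param predictor Numeric vector (e.g. methylation beta or dosage).
#' @param link_slope Target Ct change per unit predictor (cycles).
#' @param noise_sd Target Ct noise sd (cycles).
#' @param baseline_ct Target Ct at predictor 0 (cycles).
#' @param gene Gene label for the output table.
#' @param sample_id Optional sample ids (default `S001`...).
#' @param seed Optional seed.
#' @return Ct tibble compatible with [relative_expression()].
#' @examples
#' simulate_expression(runif(5), link_slope = 2, seed = 1)
#' @export
simulate_expression <- function(predictor, link_slope = 2, noise_sd = 0.5,
                                baseline_ct = 25, gene = "GENE",
                                sample_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(predictor)
  sample_id <- sample_id %||% sprintf("S%03d", seq_len(n))
  tibble::tibble(
    sample_id = sample_id, gene = gene,
    ct_target = baseline_ct + link_slope * predictor + rnorm(n, 0, noise_sd),
    ct_18s = rnorm(n, 10, 0.2),
    ct_gapdh = rnorm(n, 20, 0.2),
    ct_hprt1 = rnorm(n, 24, 0.2))
}

# E[plogis(m + sd * Z)] for Z ~ N(0,1), by quadrature
expected_inv_logit <- function(m, sd) {
  if (sd == 0) return(plogis(m))
  integrate(function(z) plogis(m + sd * z) * dnorm(z), -8, 8,
            rel.tol = 1e-10)$value
}

# Population OLS slope (per minor allele) of beta on dosage implied by the
# logit-scale generative model, averaging over offset groups.
pop_beta_slope <- function(baseline_logit, effect_logit_risk, maf,
                           risk_is_minor, noise_sd,
                           offset_values = 0, offset_weights = 1) {
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)  # minor dosage 0,1,2
  d_minor <- 0:2
  d_risk <- if (risk_is_minor) d_minor else 2 - d_minor
  mu <- vapply(seq_along(d_minor), function(i) {
    sum(offset_weights * vapply(offset_values, function(off) {
      expected_inv_logit(baseline_logit + effect_logit_risk * d_risk[i] + off,
                         noise_sd)
    }, numeric(1))) / sum(offset_weights)
  }, numeric(1))
  ed <- sum(p * d_minor)
  cov <- sum(p * (d_minor - ed) * (mu - sum(p * mu)))
  cov / sum(p * (d_minor - ed)^2)
}

probe_offset_groups <- function(config, probe_id) {
  go <- config$group_offsets[config$group_offsets$probe_id == probe_id, ]
  so <- config$sex_offsets[config$sex_offsets$probe_id == probe_id, ]
  n_tot <- config$n_oa_knee + config$n_oa_hip + config$n_nof
  w_status <- c(OA = (config$n_oa_knee + config$n_oa_hip) / n_tot,
                NOF = config$n_nof / n_tot)
  off_status <- c(OA = 0, NOF = 0)
  if (nrow(go) > 0L) {
    for (i in seq_len(nrow(go))) {
      off_status[go$status[i]] <- off_status[go$status[i]] +
        go$offset_logit[i]
    }
  }
  off_sex <- c(male = 0, female = 0)
  if (nrow(so) > 0L) {
    for (i in seq_len(nrow(so))) {
      off_sex[so$sex[i]] <- off_sex[so$sex[i]] + so$offset_logit[i]
    }
  }
  grid <- expand.grid(status = names(off_status), sex = names(off_sex),
                      stringsAsFactors = FALSE)
  list(values = off_status[grid$status] + off_sex[grid$sex],
       weights = w_status[grid$status] * 0.5)
}

#' Simulate a full discovery cohort with a planted-effect truth ledger
#'
#' Generates sample sheet, per-locus genotype dosages, a methylation
#' beta-value matrix over every region probe, a probe manifest (planted
#' CpGs at their real positions plus uniformly placed filler probes and a
#' small number of flagged polymorphic probes) and a truth ledger recording
#' each planted effect on the logit scale and as the implied
#' population-level beta-scale regression slope per minor allele (computed
#' by quadrature under the generative model, averaging over disease-group
#' and sex offsets).
#'
#' @param config A [sim_config()].
#' @param seed Root seed (default `config$seed`); per-stage substreams are
#'   derived from it.
#' @return A list of class `meqtl_cohort`: `samples`, `dosages`, `betas`,
#'   `manifest`, `loci`, `truth`, `config`, `seed`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1))
#' cohort
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4)

  n_tot <- config$n_oa_knee + config$n_oa_hip + config$n_nof
  set.seed(stage_seeds[1])
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_tot)),
    status = rep(c("OA", "OA", "NOF"),
                 c(config$n_oa_knee, config$n_oa_hip, config$n_nof)),
    joint = rep(c("knee", "hip", "hip"),
                c(config$n_oa_knee, config$n_oa_hip, config$n_nof)),
    sex = sample(c("male", "female"), n_tot, replace = TRUE))

  loci <- build_windows(config$loci)

  set.seed(stage_seeds[2])
  manifest <- purrr::map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    pl <- config$planted[config$planted$locus_id == l$locus_id, ]
    n_fill <- l$n_region_probes - nrow(pl)
    if (n_fill < 0) {
      abort(sprintf("Locus %s has more planted probes than region probes.",
                    l$locus_id))
    }
    fill_pos <- sort(round(runif(n_fill, l$window_start, l$window_end)))
    n_poly <- rbinom(1, l$n_region_probes, config$polymorphic_rate)
    poly_pos <- round(runif(n_poly, l$window_start, l$window_end))
    tibble::tibble(
      probe_id = c(pl$probe_id,
                   sprintf("cg_%s_%04d", l$locus_id,
                           seq_len(n_fill + n_poly))),
      chromosome = l$chromosome,
      position = c(pl$position, fill_pos, poly_pos),
      polymorphic = c(rep(FALSE, nrow(pl) + n_fill), rep(TRUE, n_poly)),
      locus_id = l$locus_id)
  }) |> purrr::list_rbind()

  set.seed(stage_seeds[3])
  dosages <- tibble::tibble(sample_id = samples$sample_id)
  for (i in seq_len(nrow(loci))) {
    dosages[[loci$snp_id[i]]] <- simulate_genotypes(n_tot, loci$sim_maf[i])
  }

  set.seed(stage_seeds[4])
  baselines <- runif(nrow(manifest), config$baseline_logit_range[1],
                     config$baseline_logit_range[2])
  names(baselines) <- manifest$probe_id

  beta_mat <- matrix(NA_real_, nrow = n_tot, ncol = nrow(manifest),
                     dimnames = list(NULL, manifest$probe_id))
  status_of <- samples$status
  sex_of <- samples$sex
  for (j in seq_len(nrow(manifest))) {
    pid <- manifest$probe_id[j]
    lid <- manifest$locus_id[j]
    l <- loci[loci$locus_id == lid, ]
    pl <- config$planted[config$planted$probe_id == pid &
                           config$planted$locus_id == lid, ]
    d_minor <- dosages[[l$snp_id]]
    d_risk <- if (l$risk_allele == l$minor_allele) d_minor else 2 - d_minor
    lin <- baselines[j] +
      (if (nrow(pl) == 1L) pl$effect_logit * d_risk else 0)
    go <- config$group_offsets[config$group_offsets$probe_id == pid, ]
    for (i in seq_len(nrow(go))) {
      lin <- lin + ifelse(status_of == go$status[i], go$offset_logit[i], 0)
    }
    so <- config$sex_offsets[config$sex_offsets$probe_id == pid, ]
    for (i in seq_len(nrow(so))) {
      lin <- lin + ifelse(sex_of == so$sex[i], so$offset_logit[i], 0)
    }
    beta_mat[, j] <- inv_logit_clamped(lin + rnorm(n_tot, 0,
                                                   config$noise_sd_logit))
  }
  betas <- dplyr::bind_cols(tibble::tibble(sample_id = samples$sample_id),
                            tibble::as_tibble(beta_mat))

  truth <- purrr::map(seq_len(nrow(config$planted)), function(i) {
    pl <- config$planted[i, ]
    l <- loci[loci$locus_id == pl$locus_id, ]
    risk_is_minor <- l$risk_allele == l$minor_allele
    off <- probe_offset_groups(config, pl$probe_id)
    slope <- pop_beta_slope(baselines[pl$probe_id], pl$effect_logit,
                            l$sim_maf, risk_is_minor,
                            config$noise_sd_logit, off$values, off$weights)
    tibble::tibble(
      locus_id = pl$locus_id, probe_id = pl$probe_id, snp_id = l$snp_id,
      maf = l$sim_maf, baseline_logit = unname(baselines[pl$probe_id]),
      effect_logit = pl$effect_logit, risk_is_minor = risk_is_minor,
      effect_beta_minor = slope,
      effect_beta_risk = if (risk_is_minor) slope else -slope)
  }) |> purrr::list_rbind()

  structure(list(samples = samples, dosages = dosages, betas = betas,
                 manifest = dplyr::select(manifest, -"locus_id"),
                 loci = loci, truth = truth, config = config, seed = seed),
            class = "meqtl_cohort")
}

#' @export
print.meqtl_cohort <- function(x, ...) {
  cat(sprintf(
    "<meqtl_cohort> %d samples (%d OA knee / %d OA hip / %d NOF), %d loci, %d probes (%d planted effects)\n",
    nrow(x$samples),
    sum(x$samples$status == "OA" & x$samples$joint == "knee"),
    sum(x$samples$status == "OA" & x$samples$joint == "hip"),
    sum(x$samples$status == "NOF"),
    nrow(x$loci), nrow(x$manifest), nrow(x$truth)))
  invisible(x)
}

#' Simulate a replication cohort with pyrosequencing duplicates
#'
#' Draws a fresh patient set (default 26 OA knee, 14 OA hip, 5 NOF),
#' regenerates genotypes and true methylation at the planted CpGs under the
#' same generative model as [simulate_cohort()], and measures each CpG in
#' PCR duplicate with `config$pyro_replicate_sd` percentage points of
#' replicate noise.
#'
#' Baselines at the planted CpGs are redrawn unless a discovery `cohort`
#' is supplied, in which case its truth-ledger baselines are reused so the
#' two stages share the planted effect exactly.
#'
#' @param config A [sim_config()].
#' @param n_oa_knee,n_oa_hip,n_nof Replication group sizes (26/14/5).
#' @param cohort Optional discovery `meqtl_cohort` whose planted baselines
#'   to reuse.
#' @param seed Optional seed.
#' @return List: `samples`, `dosages`, `pyro` (sample_id, cpg_id, rep1,
#'   rep2), `truth`.
#' @examples
#' rep <- simulate_replication(sim_config(), seed = 2)
#' head(rep$pyro)
#' @export
simulate_replication <- function(config = sim_config(), n_oa_knee = 26,
                                 n_oa_hip = 14, n_nof = 5, cohort = NULL,
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_tot <- n_oa_knee + n_oa_hip + n_nof
  samples <- tibble::tibble(
    sample_id = sprintf("R%03d", seq_len(n_tot)),
    status = rep(c("OA", "OA", "NOF"), c(n_oa_knee, n_oa_hip, n_nof)),
    joint = rep(c("knee", "hip", "hip"), c(n_oa_knee, n_oa_hip, n_nof)),
    sex = sample(c("male", "female"), n_tot, replace = TRUE))

  planted <- config$planted
  loci <- config$loci
  snps <- unique(loci$snp_id[loci$locus_id %in% planted$locus_id])
  dosages <- tibble::tibble(sample_id = samples$sample_id)
  for (s in snps) {
    dosages[[s]] <- simulate_genotypes(n_tot,
                                       loci$sim_maf[loci$snp_id == s])
  }

  pyro <- purrr::map(seq_len(nrow(planted)), function(i) {
    pl <- planted[i, ]
    l <- loci[loci$locus_id == pl$locus_id, ]
    base <- if (!is.null(cohort)) {
      cohort$truth$baseline_logit[cohort$truth$probe_id == pl$probe_id]
    } else runif(1, config$baseline_logit_range[1],
                 config$baseline_logit_range[2])
    d_minor <- dosages[[l$snp_id]]
    d_risk <- if (l$risk_allele == l$minor_allele) d_minor else 2 - d_minor
    lin <- base + pl$effect_logit * d_risk
    go <- config$group_offsets[config$group_offsets$probe_id ==
                                 pl$probe_id, ]
    for (g in seq_len(nrow(go))) {
      lin <- lin + ifelse(samples$status == go$status[g],
                          go$offset_logit[g], 0)
    }
    so <- config$sex_offsets[config$sex_offsets$probe_id == pl$probe_id, ]
    for (g in seq_len(nrow(so))) {
      lin <- lin + ifelse(samples$sex == so$sex[g], so$offset_logit[g], 0)
    }
    beta_true <- inv_logit_clamped(lin + rnorm(n_tot, 0,
                                               config$noise_sd_logit))
    dplyr::bind_cols(
      tibble::tibble(sample_id = samples$sample_id, cpg_id = pl$probe_id),
      simulate_pyro(beta_true, config$pyro_replicate_sd))
  }) |> purrr::list_rbind()

  list(samples = samples, dosages = dosages, pyro = pyro,
       truth = planted)
}
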