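# Tabular I/O. Everything is tab-separated with a header row so inputs and
# outputs diff cleanly and round-trip losslessly.

read_tsv_quiet <- function(file, ...) {
  readr::read_tsv(file, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a locus definition table
#'
#' One row per index SNP with columns matching [oa_loci()] (at minimum
#' `locus_id`, `snp_id`, `chromosome`, `position`, `major_allele`,
#' `minor_allele`, `risk_allele`, `ld_start`, `ld_end`, `stratum`;
#' `proxy_snp`/`proxy_r2` optional but must be present or absent together
#' per row).
#'
#' @param file Path to a tab-separated locus file.
#' @return A tibble.
#' @export
read_loci <- function(file) {
  loci <- read_tsv_quiet(file, col_types = readr::cols(
    chromosome = readr::col_character()))
  required <- c("locus_id", "snp_id", "chromosome", "position",
                "major_allele", "minor_allele", "risk_allele",
                "ld_start", "ld_end", "stratum")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0L) {
    abort(paste0("Locus file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(loci$risk_allele == loci$major_allele |
                   loci$risk_allele == loci$minor_allele))
  if (length(bad) > 0L) {
    abort(sprintf("Risk allele is neither major nor minor in row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (all(c("proxy_snp", "proxy_r2") %in% names(loci))) {
    bad <- which(is.na(loci$proxy_snp) != is.na(loci$proxy_r2))
    if (length(bad) > 0L) {
      abort(sprintf(
        "proxy_snp and proxy_r2 must be present together (row(s): %s).",
        paste(bad, collapse = ", ")))
    }
  }
  loci
}

#' Read a CpG probe manifest
#'
#' Tab-separated columns `probe_id`, `chromosome`, `position`,
#' `polymorphic` (0/1 or logical). Duplicate probe ids are rejected.
#'
#' @param file Path to the manifest.
#' @return A tibble with logical `polymorphic`.
#' @export
read_manifest <- function(file) {
  m <- read_tsv_quiet(file, col_types = readr::cols(
    chromosome = readr::col_character()))
  required <- c("probe_id", "chromosome", "position", "polymorphic")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    abort(paste0("Manifest is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$probe_id)) {
    abort(sprintf("Duplicate probe_id in manifest: %s",
                  paste(unique(m$probe_id[duplicated(m$probe_id)]),
                        collapse = ", ")))
  }
  if (any(m$position < 1)) abort("Manifest positions must be >= 1.")
  dplyr::mutate(m, polymorphic = as.logical(.data$polymorphic))
}

#' Read and validate a cohort from tab-separated files
#'
#' Assembles the discovery-scan input: sample sheet (`sample_id`, `status`
#' OA/NOF, `joint` knee/hip/none, `sex`), minor-allele dosage table
#' (`sample_id` + one column per SNP, values 0/1/2 or missing), methylation
#' beta matrix (`sample_id` + one column per probe, values in \[0, 1\] or
#' missing; or probes-by-samples with `beta_orientation =
#' "probes_by_samples"`, where the first column is `probe_id`) and a probe
#' manifest. Violations are reported with row/column coordinates; sample
#' ids must agree across the three sample-indexed tables.
#'
#' @param sample_file,dosage_file,beta_file,manifest_file File paths.
#' @param locus_file Optional locus file ([read_loci()]); default panel is
#'   [oa_loci()].
#' @param beta_orientation Orientation of the beta matrix on disk.
#' @return A `meqtl_cohort` list (`samples`, `dosages`, `betas`,
#'   `manifest`, `loci`).
#' @export
read_cohort <- function(sample_file, dosage_file, beta_file, manifest_file,
                        locus_file = NULL,
                        beta_orientation = c("samples_by_probes",
                                             "probes_by_samples")) {
  beta_orientation <- match.arg(beta_orientation)
  samples <- read_tsv_quiet(sample_file)
  required <- c("sample_id", "status", "joint", "sex")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    abort(paste0("Sample sheet is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf("Duplicate sample_id in sample sheet: %s",
                  paste(unique(samples$sample_id[
                    duplicated(samples$sample_id)]), collapse = ", ")))
  }
  bad <- which(!samples$status %in% c("OA", "NOF") |
                 !samples$joint %in% c("knee", "hip", "none") |
                 !samples$sex %in% c("male", "female"))
  if (length(bad) > 0L) {
    abort(sprintf("Invalid status/joint/sex in sample sheet row(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  bad <- which(samples$status == "NOF" & samples$joint == "knee")
  if (length(bad) > 0L) {
    abort(sprintf(
      "NOF samples must have joint 'hip' or 'none' (row(s): %s).",
      paste(bad, collapse = ", ")))
  }

  dosages <- read_tsv_quiet(dosage_file)
  check_cells(dosages, function(x) x %in% c(0, 1, 2),
              "dosage outside {0, 1, 2}")

  betas <- read_tsv_quiet(beta_file)
  if (beta_orientation == "probes_by_samples") {
    betas <- transpose_beta(betas)
  }
  check_cells(betas, function(x) x >= 0 & x <= 1, "beta outside [0, 1]")

  manifest <- read_manifest(manifest_file)
  loci <- if (is.null(locus_file)) oa_loci() else read_loci(locus_file)

  for (nm in c("dosages", "betas")) {
    tbl <- get(nm)
    extra <- setdiff(tbl$sample_id, samples$sample_id)
    missing_ids <- setdiff(samples$sample_id, tbl$sample_id)
    if (length(extra) + length(missing_ids) > 0L) {
      abort(sprintf(
        "Sample ids in %s do not match the sample sheet (unknown: %s; absent: %s)",
        nm,
        paste(extra, collapse = ", ") %e% "none",
        paste(missing_ids, collapse = ", ") %e% "none"))
    }
  }
  probe_cols <- setdiff(names(betas), "sample_id")
  unknown <- setdiff(probe_cols, manifest$probe_id)
  if (length(unknown) > 0L) {
    abort(sprintf("Beta matrix has probes absent from the manifest: %s",
                  paste(head(unknown, 10), collapse = ", ")))
  }

  structure(list(samples = samples, dosages = dosages, betas = betas,
                 manifest = manifest, loci = loci),
            class = "meqtl_cohort")
}

`%e%` <- function(x, default) if (nzchar(x)) x else default

transpose_beta <- function(betas) {
  stopifnot("probe_id" %in% names(betas))
  probe_ids <- betas$probe_id
  mat <- t(as.matrix(betas[setdiff(names(betas), "probe_id")]))
  colnames(mat) <- probe_ids
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(mat)),
                   tibble::as_tibble(mat))
}

check_cells <- function(tbl, ok_fun, what) {
  for (col in setdiff(names(tbl), "sample_id")) {
    x <- tbl[[col]]
    bad <- which(!is.na(x) & !ok_fun(x))
    if (length(bad) > 0L) {
      abort(sprintf("Invalid value (%s) at row %d, column '%s': %s",
                    what, bad[1], col, format(x[bad[1]])))
    }
  }
  invisible(tbl)
}

#' Write a cohort to tab-separated files
#'
#' Emits `samples.tsv`, `dosages.tsv`, `betas.tsv`, `manifest.tsv` and
#' `loci.tsv` into `dir`; the layout read back by [read_cohort()].
#'
#' @param cohort A `meqtl_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$dosages, file.path(dir, "dosages.tsv"))
  readr::write_tsv(cohort$betas, file.path(dir, "betas.tsv"))
  readr::write_tsv(
    dplyr::mutate(cohort$manifest,
                  polymorphic = as.integer(.data$polymorphic)),
    file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$loci, file.path(dir, "loci.tsv"))
  invisible(dir)
}

#' Export analysis windows or LD blocks as BED intervals
#'
#' Converts the package's 1-based inclusive intervals to the BED dialect
#' (0-based half-open) for genome-browser use.
#'
#' @param loci Output of [build_windows()] (uses the window columns), or any
#'   tibble with `chromosome`, `start`, `end` columns plus an id column.
#' @param what `"window"` (default) or `"ld_block"`.
#' @return Tibble with `chrom`, `chromStart`, `chromEnd`, `name`.
#' @examples
#' windows_to_bed(build_windows(oa_loci()))
#' @export
windows_to_bed <- function(loci, what = c("window", "ld_block")) {
  what <- match.arg(what)
  if (what == "window") {
    start <- loci$window_start
    end <- loci$window_end
  } else {
    start <- loci$ld_start
    end <- loci$ld_end
  }
  name <- loci$snp_id %||% loci$locus_id %||%
    as.character(seq_len(nrow(loci)))
  tibble::tibble(chrom = paste0("chr", loci$chromosome),
                 chromStart = as.integer(start - 1),
                 chromEnd = as.integer(end),
                 name = paste0(name, "_", what))
}
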