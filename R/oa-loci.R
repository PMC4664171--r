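#' Built-in table of the 16 osteoarthritis association signals
#'
#' Returns the reference panel of 16 OA susceptibility loci used throughout
#' the package: one index SNP per locus with hg19 position, major/minor
#' alleles, the OA risk allele where the source studies name one, the LD-block
#' interval (r\eqn{^2} > 0.8 with the index SNP), the joint/sex stratum in
#' which the genetic association was originally reported, proxy-SNP metadata
#' for index SNPs absent from the genotyping array, and the number of 450k
#' CpG probes falling in the analysis region around each SNP.
#'
#' Only the rs10948172 LD block (chr6:44,683,049-45,349,877, ~667 kb) has
#' published bounds; the other 15 blocks are synthetic placeholders spanning
#' +/-100 kb around the SNP, flagged by `ld_synthetic`. They sit inside the
#' 1 Mb default analysis window, so window construction behaves as for the
#' real loci (1 Mb suffices for 15 loci; rs10948172 requires 1.5 Mb).
#'
#' The OA risk allele is published for the four meQTL loci (rs6976 T,
#' rs10948172 G, rs3204689 C, rs143383 T). For the remaining 12 the minor
#' allele is used as a placeholder, flagged by `risk_synthetic`; it only
#' affects direction labelling at those loci. `sim_maf` is a synthetic
#' common-variant minor-allele frequency consumed by the cohort generator
#' (true cohort MAFs are not part of this panel).
#'
#' @return A tibble with one row per locus and columns `locus_id`, `snp_id`,
#'   `chromosome`, `position`, `major_allele`, `minor_allele`, `risk_allele`,
#'   `risk_synthetic`, `ld_start`, `ld_end`, `ld_synthetic`, `stratum`,
#'   `proxy_snp`, `proxy_r2`, `n_region_probes`, `sim_maf`.
#' @examples
#' oa_loci()
#' @export
oa_loci <- function() {
  loci <- tibble::tribble(
    ~locus_id, ~snp_id, ~chromosome, ~position, ~major_allele, ~minor_allele,
    ~risk_allele, ~risk_synthetic, ~stratum, ~proxy_snp, ~proxy_r2,
    ~n_region_probes, ~sim_maf,
    "GLT8D1",  "rs6976",     "3",  52703844L,  "C", "T", "T", FALSE, "knees and hips", NA_character_, NA_real_, 431L, 0.42,
    "TP63",    "rs12107036", "3",  191082854L, "G", "A", "A", TRUE,  "female knees",   NA_character_, NA_real_, 76L,  0.38,
    "SUPT3H",  "rs10948172", "6",  44777691L,  "A", "G", "G", FALSE, "males",          NA_character_, NA_real_, 197L, 0.32,
    "FILIP1",  "rs9350591",  "6",  76298247L,  "C", "T", "T", TRUE,  "hips",           "rs7756065",   1.0,      157L, 0.12,
    "COG5",    "rs3815148",  "7",  106938420L, "A", "C", "C", TRUE,  "knees",          "rs1548524",   1.0,      135L, 0.23,
    "ASTN2",   "rs4836732",  "9",  118306516L, "T", "C", "C", TRUE,  "female hips",    NA_character_, NA_real_, 57L,  0.47,
    "KLHDC5",  "rs10492367", "12", 27906237L,  "G", "T", "T", TRUE,  "hips",           "rs10843013",  1.0,      123L, 0.19,
    "CHST11",  "rs835487",   "12", 103584897L, "A", "G", "G", TRUE,  "hips",           NA_character_, NA_real_, 190L, 0.34,
    "MCF2L",   "rs11842874", "13", 113694259L, "A", "G", "G", TRUE,  "knees and hips", NA_character_, NA_real_, 655L, 0.07,
    "DIO2",    "rs225014",   "14", 80669330L,  "T", "C", "C", TRUE,  "hips",           NA_character_, NA_real_, 32L,  0.39,
    "DIO3",    "rs945006",   "14", 102029277L, "T", "G", "G", TRUE,  "knees and hips", NA_character_, NA_real_, 385L, 0.21,
    "ALDH1A2", "rs3204689",  "15", 58246802L,  "C", "G", "C", FALSE, "hands",          NA_character_, NA_real_, 91L,  0.44,
    "FTO",     "rs8044769",  "16", 53839135L,  "C", "T", "T", TRUE,  "females",        NA_character_, NA_real_, 92L,  0.48,
    "DOT1L",   "rs12982744", "19", 2177193L,   "C", "G", "G", TRUE,  "male hips",      NA_character_, NA_real_, 135L, 0.36,
    "NCOA3",   "rs6094710",  "20", 46095649L,  "G", "A", "A", TRUE,  "hips",           NA_character_, NA_real_, 71L,  0.10,
    "GDF5",    "rs143383",   "20", 34025983L,  "T", "C", "T", FALSE, "knees and hips", "rs6087704",   0.93,     270L, 0.40
  )
  loci <- dplyr::mutate(
    loci,
    ld_start = dplyr::if_else(.data$snp_id == "rs10948172",
                              44683049L, .data$position - 100000L),
    ld_end = dplyr::if_else(.data$snp_id == "rs10948172",
                            45349877L, .data$position + 100000L),
    ld_synthetic = .data$snp_id != "rs10948172"
  )
  dplyr::relocate(loci, "ld_start", "ld_end", "ld_synthetic",
                  .after = "risk_synthetic")
}

#' CpG probes with genotype-associated methylation at the four cartilage meQTLs
#'
#' The nine 450k CpG probes whose methylation tracks index-SNP genotype in
#' cartilage: three at the GLT8D1/rs6976 locus (in the STAB1 gene body,
#' upstream of the LD block), four adjacent CpGs at the SUPT3H/rs10948172
#' locus (inside its LD block), one in the ALDH1A2 gene body at rs3204689 and
#' one upstream of the GDF5 TSS at rs143383. At all four loci the OA risk
#' allele is associated with lower methylation. The synthetic-cohort
#' generator plants its default effects at these probes and positions.
#'
#' @return A tibble with columns `probe_id`, `locus_id`, `snp_id`,
#'   `chromosome`, `position` (hg19, 1-based).
#' @examples
#' dplyr::count(oa_meqtl_cpgs(), locus_id)
#' @export
oa_meqtl_cpgs <- function() {
  tibble::tribble(
    ~probe_id,    ~locus_id, ~snp_id,      ~chromosome, ~position,
    "cg18099408", "GLT8D1",  "rs6976",     "3",  52552593L,
    "cg15147215", "GLT8D1",  "rs6976",     "3",  52552868L,
    "cg18591801", "GLT8D1",  "rs6976",     "3",  52553433L,
    "cg13979708", "SUPT3H",  "rs10948172", "6",  44695318L,
    "cg19254793", "SUPT3H",  "rs10948172", "6",  44695348L,
    "cg20913747", "SUPT3H",  "rs10948172", "6",  44695427L,
    "cg18551225", "SUPT3H",  "rs10948172", "6",  44695536L,
    "cg12031962", "ALDH1A2", "rs3204689",  "15", 58353849L,
    "cg14752227", "GDF5",    "rs143383",   "20", 34000481L
  )
}
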