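Package: meqtlscan
Title: Cis-meQTL Mapping of Osteoarthritis Risk Loci in Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis-acting methylation quantitative trait loci (meQTLs) at
    disease-associated index SNPs. Builds LD-block-anchored analysis windows
    around each index SNP, regresses CpG methylation beta-values on
    minor-allele dosage with region-wise Benjamini-Hochberg false discovery
    rate control and stratified rescans, replicates hits on duplicate-QC'd
    pyrosequencing percent-methylation data with Kruskal-Wallis tests and
    Bonferroni correction, and integrates methylation with relative gene
    expression measured by the 2^-deltaCt method. Includes a synthetic cohort
    generator with a planted-effect truth ledger for power and
    false-discovery-rate validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
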