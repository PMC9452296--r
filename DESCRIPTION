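Package: editqc
Title: Genome-Integrity Quality Control for CRISPR-Engineered Cell Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control analyses for CRISPR-Cas9 edited (e.g. non-viral
    CAR-T) cell products. Enumerates candidate off-target sites genome-wide
    under a mismatch-plus-bulge penalty budget with a PAM constraint,
    cross-references whole-genome-sequencing indel calls between edited and
    control samples against windows around candidate sites, quantifies
    per-locus indel and knock-in (HDR) percentages from amplicon deep
    sequencing reads, and deconvolves wild-type/heterozygous/homozygous
    knock-in genotype fractions from semiquantitative three-primer PCR band
    intensities. Includes seed-deterministic synthetic-data generators with
    machine-readable ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    vcfR,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
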