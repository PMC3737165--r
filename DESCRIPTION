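Package: nullscan
Title: Null Allele and Deletion Detection from SNP Genotypes in
    Three-Generation Intercross Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects possible null alleles (non-amplifying marker alleles) at
    biallelic SNPs genotyped in three-generation intercross families, using
    Mendelian incompatibilities and missing-value patterns across F0
    grandparents, F1 parents and F2 offspring. Each SNP is placed per family
    into one of five null-allele evidence classes, two genotyping-error
    categories, or called consistent, and family results are integrated into
    an overall per-SNP category. A family-ratio mixture model estimates the
    fraction of each null-allele class attributable to genotyping error, and
    candidate deletions are called from linked null alleles at adjacent
    markers. A gene-drop simulator with injected null alleles, deletion runs,
    genotyping errors and missingness provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
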