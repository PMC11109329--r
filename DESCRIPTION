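Package: famseg
Title: Family-Based Rare-Variant Segregation Analysis for Cancer Predisposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for germline variant analysis in multiplex cancer families:
    pedigree input with founder-lineage ("tumor side") bookkeeping and Mendelian
    checks, VCF and annotation-table input, a discovery-stage frequency and
    consequence filter with targeted-panel genotype quality control,
    pedigree-aware segregation classification with inheritance-side inference,
    all-criteria prioritization of rare damaging variants at the variant and
    gene level, known risk-locus summaries with polygenic risk score permutation
    comparison, family-design detection-power estimation, and a tumor/normal
    loss-of-heterozygosity screen. Includes a gene-drop simulator of multiplex
    families with an incompletely penetrant causal allele and a deterministic
    synthetic worked-example cohort of Finnish familial glioma pedigrees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
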