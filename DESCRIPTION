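Package: saltqtl
Title: Bulk-Segregant QTL Mapping of NaCl Tolerance in a Biparental Yeast Cross
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dissecting NaCl-tolerance genetics
    in a biparental Saccharomyces cerevisiae cross (BY x CEN.PK). Provides a forward
    simulator of meiosis, iterative backcrossing with truncation selection and pooled
    sequencing; colony-size plate normalization, tolerance class binning and growth
    curve parameter extraction; Gaussian-mixture modality calls with a BIC rule;
    bulk-segregant allele-frequency QTL mapping with the tricube-smoothed G'
    statistic and a robust lognormal null; and asparagine-homorepeat allele
    classification with ENA-dose-stratified association tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    patchwork,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
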