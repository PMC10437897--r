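Package: mlidscan
Title: Genome-Wide Detection of Multi-Locus Imprinting Disturbance from
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-case analysis of genome-wide DNA methylation (beta-value)
    data for imprinting disorders. Implements probe-level quality control,
    per-sample beta-mixture quantile (BMIQ) normalization of Infinium type II
    probes, Crawford-Howell single-case t-tests of one patient against a small
    control group, calling of differentially methylated positions and aberrant
    imprinted differentially methylated regions (iDMRs), epigenotype assignment
    at the 11p15.5 imprinting control regions, and classification of
    multi-locus imprinting disturbance (MLID). Also provides cohort-level
    group comparisons with hierarchical clustering, clinical scoring
    (Beckwith-Wiedemann consensus score, Netchine-Harbison score,
    pyrosequencing standard-deviation scores), and a synthetic-cohort
    generator with planted epimutations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
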