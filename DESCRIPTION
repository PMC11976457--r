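Package: sclcscars
Title: Genomic Scars, UPD and Double-Hit Analysis for Transformed and De
    Novo Small Cell Lung Cancer Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream whole-exome analysis for contrasting transformed
    small cell lung cancer (SCLC), de novo SCLC and primary lung
    adenocarcinoma cohorts. Implements dual-caller consensus somatic
    variant filtering (matched and tumor-only panel-of-normals paths),
    allele-specific copy-number classification with copy-neutral LOH
    (uniparental disomy) detection, chromosome-arm event aggregation,
    genomic-scar scoring (HRD-LOH, telomeric allelic imbalance,
    large-scale state transitions), Knudson double-hit integration of
    mutations with copy loss and UPD, COSMIC-style single-base
    substitution signature deconvolution by non-negative least squares,
    tumor mutational burden, and cohort statistics (exact Wilcoxon and
    Fisher tests with BH adjustment). A seeded synthetic-cohort
    generator emulates the study's group structure so the full pipeline
    is testable without any sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
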