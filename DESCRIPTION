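Package: soilmfc
Title: Analysis Pipeline for Soil Microbial Fuel Cell Antibiotic Remediation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of soil microbial fuel cell (MFC) antibiotic
    remediation experiments: electrochemical performance metrics (current and
    power density, accumulated charge, start-up time, polarization-curve fits
    for open-circuit voltage and internal resistance), antibiotic removal
    efficiency with one-way ANOVA and Duncan's multiple range letters,
    high-throughput qPCR quantification of antibiotic resistance genes with
    well-level quality control and 16S normalization, alpha-diversity
    summaries of bacterial, fungal and archaeal communities, and multi-kingdom
    Spearman co-occurrence network inference with keystone filtering, topology
    reports and MCODE submodule detection. A synthetic-data module emulates
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
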