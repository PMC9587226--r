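Package: oglyco
Title: Differential O-Glycoproteomics, Glycan-Patch Detection and Site-Occupancy Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for mucin-type O-glycoproteomics of
    GalNAc-transferase knockout panels. Aggregates glycopeptide-spectrum matches
    into a localization-filtered catalog of protein-coordinate O-glycosylation
    sites, maps sites onto protein regions (domains, stems, linkers, termini,
    functional regions), detects high-density glycan patches (mucin-like
    regions), calls isoform-specific site regulation from multiplexed TMT
    reporter intensities (normalization, protein-abundance correction, t-tests,
    FDR control), and estimates per-peptide O-glycosylation occupancy from MS1
    glycoform peak areas. A synthetic-data generator provides ground-truth
    proteomes, PSM tables and peak tables so every stage is testable without
    deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
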