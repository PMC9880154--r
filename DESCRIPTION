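Package: methylotrace
Title: Promoter Methylation Analysis from Direct Bisulfite Sanger Traces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies per-CpG DNA methylation from direct (pooled-molecule)
    bisulfite Sanger sequencing chromatograms using C/T peak-intensity ratios,
    detects CpG islands and short CpG islets with Gardiner-Garden-Frommer
    composition criteria, scans promoter elements for transcription-factor
    binding sites with a MATCH-style matrix similarity score, and compares
    region-grouped methylation across developmental stages with
    repeated-measures ANOVA, delta-delta-Ct relative expression, and
    methylation-expression correlation. Ships a synthetic-data module that
    simulates promoters, bisulfite-converted molecule pools, chromatograms,
    and qPCR plates with known ground truth, so every stage of the pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
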