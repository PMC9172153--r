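Package: spliceshift
Title: Junction-Based Exon Usage, Polyadenylation Readthrough and Censored
    qPCR Analysis of Systemic mRNA-Processing Defects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies systemic mRNA-processing defects from bulk RNA-seq
    evidence in a case/control (wild-type versus mutant) design. Implements
    junction-based differential exon usage (skip and inclusion counting per
    annotated exon, expression-normalised rates, signed contrast and Welch
    t-test), transcriptional readthrough scoring in a fixed window downstream
    of annotated polyadenylation sites, correlation of 5-mer sequence
    composition around exon boundaries with exon-usage shifts, and a censored
    delta-Ct analysis of qPCR detection-limit data. A fully deterministic
    synthetic-data generator with planted splicing and readthrough events
    provides ground truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
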