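Package: cobascreen
Title: Affinity-Probe Enrichment Screens and Cobamide-Transporter
    Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-enrichment analysis of affinity-based-probe
    chemoproteomics screens from label-free quantification (LFQ) protein
    tables: replicate-presence filtering, left-censored missing-value
    imputation, right-tailed two-sample t tests, Benjamini-Hochberg false
    discovery rate control, and cross-screen intersection of hits. Also
    implements a comparative-genomics survey of cobamide-transport gene
    (btuH) homologs from BLAST tabular hits -- E-value homolog calling,
    N-terminal domain-architecture assignment, operon classification --
    and the associated statistics (chi-square test of independence and
    tie-aware Spearman rank correlation, with tail probabilities computed
    from the regularized incomplete gamma and beta functions). A
    synthetic-data module generates LFQ screens and genome panels with
    planted ground truth so the full pipeline is testable without raw
    mass-spectrometry or genome data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
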