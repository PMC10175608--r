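Package: immsig
Title: Tumor Immune Signature Typing for Mismatch-Repair-Deficient Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies mismatch-repair-deficient tumors into the three
    tumor immune signatures (inflamed, immune excluded, immune desert) from
    two independent data modalities: spatial maps of CD8+ T-cell
    infiltration and bulk tumor/normal transcriptomes scored by gene-set
    over-representation (Fisher's exact test with Benjamini-Hochberg
    correction). Also provides reference-based immune deconvolution with
    permutation p-values and absolute-fraction composition, 12-chemokine
    tertiary-lymphoid-structure and 18-gene T-cell-inflamed signature
    scoring, five-rule tumor/normal somatic variant filtering with
    mutational-burden summaries, mutation-versus-expression pathway
    concordance, and 2x2 clinical association testing, together with
    synthetic-data generators that emulate each input with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
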