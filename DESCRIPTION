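Package: meioreg
Title: Promoter Binding and Absolute Expression Analysis of Male Meiotic
    Transcription-Factor Circuits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links transcription-factor promoter occupancy (CUT&RUN and
    ChIP-seq peak sets) to stage-specific germ-cell gene expression
    quantified in absolute units with ERCC spike-ins. Implements
    summit-to-TSS distances and promoter-window assignment,
    multi-replicate binding-evidence rules, molecules-per-cell
    calibration and cell-volume-corrected transcript concentration,
    stage-specific expression classification, a differential-expression
    filter with Benjamini-Hochberg FDR control, coherent feedforward-loop
    detection on signed regulatory graphs, gene-set binding-enrichment
    tests, and IUPAC consensus motif scanning, together with a seeded
    synthetic-data generator that plants known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
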