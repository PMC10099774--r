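Package: germselect
Title: Germline Selection Analysis of UID-Family Deep-Sequenced Testis Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring low-frequency de novo variant clusters in
    spatially dissected testes with UID-family (unique molecular identifier)
    error-corrected amplicon sequencing, and for interpreting them with
    branching-process models of spermatogonial stem cell dynamics. Includes a
    consensus variant caller for barcoded UID-tagged reads, a candidate-variant
    registry for the PTPN11 exon 3 amplicon, Galton-Watson simulators of the
    neutral and selection models of stem cell self-renewal, a Monte-Carlo
    Bonferroni envelope test for the maximum piece frequency (MaxPF) cluster
    statistic, supporting inferential statistics, a synthetic data generator
    emulating the assay's sequencing structure, and prediction of the Noonan
    syndrome birth rate from calibrated selection parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
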