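Package: lrcrosstalk
Title: Ligand-Receptor Crosstalk Discovery with Spatial Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for discovering disease-associated
    ligand-receptor interactions from paired single-cell and spatial
    transcriptomics data. Single-cell cell-cell communication is scored
    per condition with a permutation null; spatial spots are deconvolved
    into cell-type abundances, clustered by composition, and cell-type
    pairs are classified by exact hypergeometric co-occurrence; candidate
    ligand-receptor pairs must show directionally consistent differential
    expression between conditions and positive spatial co-occurrence of
    their source and target cell types, with minimum-principle spatial
    co-expression as supporting evidence. A synthetic paired-data
    generator with known ground truth (planted communication programs,
    spot compositions, co-localization structure) makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
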