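Package: senespread
Title: Quantifying Histone-Mark Spreading and Length-Dependent Transcription in Cellular Senescence
Version: 0.1.0
Authors@R:
    person("Senespread", "Developers", email = "senespread@example.org", role = c("aut", "cre"))
Description: A quantification toolkit for the chromatin signature of replicative
    senescence. Computes normalized histone-mark tag densities in strand-aware
    windows around transcription start sites and over gene bodies, scaled-gene-body
    metagene profiles, TSS-centered profile matrices, RNA polymerase II pausing
    indices from nascent-transcription coverage, combined RNA-seq/GRO-seq
    fold-change classification of senescence-regulated gene sets, gene-length
    stratified fold-change analysis, promoter mark-loss selection, and gene-set
    overlap statistics (Fisher's exact test with Jaccard index, Mann-Whitney U,
    two-tailed z-tests). Ships a synthetic-data generator that plants
    promoter-peaked versus body-spread coverage, length-biased upregulated gene
    sets, and promoter mark-loss coupled to induction, so every stage of the
    pipeline can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
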