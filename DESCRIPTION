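Package: regrec
Title: Comparative Reconstruction of Bacterial Transcription-Factor Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Position-weight-matrix based reconstruction of bacterial
    regulons across related genomes: building log-odds weight matrices from
    curated operator alignments, scanning strand-normalized upstream regions
    of annotated genes, filtering candidate sites by cross-genome consistency
    (phylogenetic footprinting), predicting operons and assembling regulons,
    classifying operator overlap with sigma70 -10/-35 promoter elements, and
    the accompanying quantification tools: four-parameter logistic EC50 fits
    with fixed asymptotes for titration assays, empirical growth-curve AUC,
    and affinity-expression correlation. Includes a ground-truthed simulator
    of genome clades with planted operators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    ape,
    minpack.lm,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
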