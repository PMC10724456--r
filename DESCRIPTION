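Package: gestenh
Title: Gestational Dynamics of Placental Enhancers and Transcription Factor Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an expressed distal enhancer universe from nascent-transcription
    (PRO-seq derived) regulatory-element calls across gestation, quantifies gene and
    enhancer expression dynamics versus gestational age, links enhancers to target
    genes, scores transcription factors with the Total Functional Score of Enhancer
    Elements (TFSEE) algorithm, and measures GWAS SNP density enrichment in enhancer
    regions. Includes a synthetic multi-omic study generator with recorded ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
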