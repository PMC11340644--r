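Package: viralhost
Title: Hierarchical Host Prediction for RNA Viruses from Genome Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the host of an RNA virus from its genome sequence alone.
    Viral genomes are encoded as genomic-trait vectors (nucleotide,
    dinucleotide, codon, amino-acid and optionally codon-pair usage
    preferences, log2-transformed) concatenated with per-host-group best-hit
    local-alignment scores, and classified by per-virus-order gradient-boosted
    models over a fixed two-layer host taxonomy (kingdom/phylum, then
    class/order under Chordata), with confidence-based rejection of
    out-of-distribution queries. Includes label screening against the host
    taxonomy, stratified cross-validation, family-wise homogeneity analysis,
    fragment-completeness and leave-one-genus-out evaluation harnesses, and a
    synthetic-genome simulator with controllable host-signal strength.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    xgboost,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    rtracklayer,
    GenomicRanges,
    IRanges,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
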