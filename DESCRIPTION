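Package: tfbstrio
Title: Sequence, Structure and Evolution Characterization of Transcription
    Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing transcription factor binding sites
    (TFBSs) with three complementary per-segment features: a position weight
    matrix score weighted by per-position information content (sequence
    feature), means of dinucleotide conformational and physicochemical
    properties (structure feature), and the conservation score of the best
    matching catalog motif (evolution feature). Includes a third-order Markov
    background generator for negative instances, decision-tree TFBS
    identification models with correlation-based feature selection evaluated
    under stratified 10-fold cross-validation, and three TF-to-TFBS
    correspondence analyses: sequence-level cluster matching, structure-level
    class mapping, and evolution-level conservation correlation. A synthetic
    world generator with planted families, structural classes and a planted
    rank correlation makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    mclust,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
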