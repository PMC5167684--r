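Package: oligoFP
Title: Sequence-Based Prediction of Fluorescent Protein Oligomeric State
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies fluorescent proteins as monomeric or oligomeric
    directly from the amino acid sequence. Implements six classes of
    protein sequence descriptors (amino acid, dipeptide and tripeptide
    composition; Moreau-Broto, Moran and Geary physicochemical
    autocorrelation; composition/transition/distribution; conjoint triad;
    sequence-order-coupling and quasi-sequence-order; pseudo and
    amphiphilic pseudo amino acid composition), greedy identity-threshold
    sequence clustering for redundancy reduction, pairwise-correlation
    feature pruning, an interpretable gain-ratio (C4.5-style) decision
    tree with pessimistic-error pruning, and a repeated 80/20 split plus
    stratified tenfold cross-validation benchmarking protocol reporting
    accuracy, sensitivity, specificity and the Matthews correlation
    coefficient, together with tree feature-usage scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Biostrings, seqinr
Suggests: testthat (>= 3.0.0), caret, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
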