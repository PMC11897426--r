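Package: plasmidhostr
Title: Multi-Label Plasmid Host Range Prediction with Pseudo-Labelling
    and a Self-Correction Asymmetric Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the genus-level host range of bacterial plasmids as a
    multi-label learning problem with missing labels. Scores the association
    between protein clusters and host genera with a TF-IDF-style statistic
    and an augmented variant that rescues small genus-specific clusters,
    assigns at most one additional pseudo host label per single-labelled
    training plasmid from the protein-cluster evidence, and trains a
    sigmoid multi-label classifier on k-mer sequence features under an
    asymmetric focal loss that, after a warm-up phase, re-interprets
    confidently predicted negative labels as missing positives. Includes
    parsers for CD-HIT cluster files and BLAST tabular output, a builder
    for multi-host test sets from near-identical cross-genus alignment
    pairs, macro-averaged evaluation metrics, and a synthetic corpus
    generator with planted marker genes and hidden dual-host plasmids so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
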