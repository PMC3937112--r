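Package: tRNAcif
Title: tRNA Class-Informative Features, Function Logos and Genome
    Phyloclassification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates function logos from structurally aligned tRNA gene
    (tDNA) sequences keyed to Sprinzl coordinates, extracts tRNA
    Class-Informative Features (CIFs), and classifies genomes into taxa by
    CIF-match scores: a binary classifier with leave-one-out
    cross-validation, total-sequence log-odds profile classifiers with four
    missing-data treatments, and a multiway classifier that feeds per-clade
    score vectors to a small multilayer perceptron with site-bootstrap
    support estimation. Includes compositional diagnostics (centered
    log-ratio transform, Aitchison distances, UPGMA clustering of tRNA base
    compositions) and a synthetic tDNA generator with planted CIFs and
    tunable A+T compositional drift for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
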