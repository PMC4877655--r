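Package: ladderlens
Title: Asparagine-Ladder Architecture Analysis of Toll-Like Receptor Ectodomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies vertebrate Toll-like receptor (TLR) ectodomains into
    single-domain, three-domain and trans-three-domain architectures from the
    asparagine-ladder pattern of their leucine-rich repeat (LRR) modules.
    Provides an LRR motif scanner with dynamic-programming module chaining,
    entropy-based conservation grading of ladder positions, distance-based
    (neighbor-joining) family clustering with reference-anchored clade
    labelling, Nei-Gojobori (1986) dN/dS estimation with Jukes-Cantor
    correction and codon-column bootstrap confidence intervals, TM-score
    structural comparison of CA traces via Kabsch superposition and iterative
    dynamic-programming alignment, and seed-deterministic synthetic-data
    generators (LRR ectodomains, ortholog families, codon alignments,
    horseshoe CA traces) with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    Matrix,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
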