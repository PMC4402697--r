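Package: pigsr
Title: Probabilistic Identity-by-Descent Graph Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Updates pairwise identity-by-descent (IBD) probabilities at a
    genomic locus by conditioning on all pairwise estimates simultaneously
    under the constraint that true IBD graphs are unions of cliques
    (transitivity). Provides exact conditional edge probabilities by
    enumeration of transitive graph configurations (set partitions) for
    small graphs, and a weighted graph-sampling approximation for larger
    ones; LOD-score calibration for Refined IBD style input, breakpoint
    region construction, cross-region merging and inference of previously
    uncalled segments; plus a segment-level synthetic-data generator and
    benchmarking metrics (power, error rate, FDR, clique edge recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
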