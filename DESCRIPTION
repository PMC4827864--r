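Package: ompbarrel
Type: Package
Title: Shuffle-Null Homology Statistics and Superfamily Inference for
    Outer-Membrane Beta-Barrel Protein Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for establishing homology among outer-membrane
    pore-forming protein (OMPP) families and grouping them into
    superfamilies. Implements Monte-Carlo shuffle-null comparison scores
    for global alignments (reported in standard deviations), transitive
    homology chains under the superfamily principle, alignment-free
    score-based family trees with consensus support, average
    hydropathy/amphipathicity/similarity profiles with a simple
    transmembrane beta-strand caller, an intra-protein beta-hairpin
    repeat scan, and a seeded generator of synthetic beta-barrel
    families with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
SystemRequirements: MAFFT (optional, used by msaTree())
Config/testthat/edition: 3
RoxygenNote: 7.3.3
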