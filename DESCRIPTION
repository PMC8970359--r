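Package: CdvArch
Title: Domain-Architecture Analysis of Archaeal Cdv/ESCRT Cell-Division Machineries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing archaeal Cdv/ESCRT cell-division machineries at
    the protein-domain level. Implements regular-expression scanning for the
    proline-anchored MIM2 motif classes and N-terminal ANCHR helix calls,
    assembly and classification of per-protein domain architectures (CdvA,
    CdvB-class taxonomy, CdvC filtering), rule-based domain-domain interaction
    networks with qualitative family-level collapsing, recursive mechanism
    inference with affinity tie-breaking and scenario forking, and
    maximum-parsimony reconstruction of domain gain and loss on a rooted
    species tree (exact Sankoff scoring, Dollo and evidence-biased root
    resolution). A synthetic-data generator plants motifs and simulates binary
    domain evolution so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
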