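Package: mirbind
Title: Hydrogen-Bond Scoring and Cluster Analysis of miRNA Binding Sites in mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of miRNA-mRNA interactions using a
    hydrogen-bond duplex scoring model that admits the non-canonical G-U
    (wobble) and A-C pairs. Slides each miRNA along annotated transcripts,
    calls binding sites by the free-energy ratio dG/dGm, groups overlapping
    sites into clusters with compaction statistics, detects polysites
    (tandem same-miRNA starts) and recurrent start offsets between miRNA
    pairs across genes, compares site clusters across orthologous mRNA
    segments (conserved flanking oligonucleotides, transition/transversion
    classification, cross-species re-scoring, peptide translation), and
    ranks miRNA-gene associations by expression context and free-energy
    marker rules. Includes seeded generators for synthetic cohorts with
    planted sites, clusters, polysites, offset pairs and ortholog sets so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
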