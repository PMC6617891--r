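Package: homoeoPhy
Title: Homoeolog Typing and Polyploid Origin Inference from Low-Copy
    Nuclear Gene Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting structural variants (homoeologs) of a
    low-copy nuclear gene in polyploid plants and for inferring allo-
    versus autopolyploid origin from their placement in a gene tree.
    Exon/intron boundaries of amplicon sequences are annotated by
    projection from an annotated reference with canonical GT..AG
    splice-site validation; sequences are classified into structural
    variants by intron-length criteria and screened for pseudogenes
    (frameshifts and internal stop codons); alignments are summarised
    (variable and parsimony-informative sites, uncorrected p-distances);
    neighbor-joining trees with nonparametric bootstrap supports are
    built; and each polyploid individual's gene copies are tested for
    monophyly and assigned to major clades to call an allopolyploid or
    autopolyploid pattern. A fully seeded sequence simulator generates
    two diverged diploid gene pools with distinct intron architectures,
    allo- and autotetraploids, intron indels, intron losses and
    pseudogenes, together with ground truth, so that every stage of the
    pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, SequenceMatching, Genetics
RoxygenNote: 7.3.3
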