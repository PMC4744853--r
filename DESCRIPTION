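Package: microevo
Title: Strain-Level Comparative Genomics of Conspecific Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for strain-level (microevolutionary) comparative genomics
    of conspecific bacterial isolates: pangenome partitioning into core,
    shared-accessory and strain-specific gene families via bidirectional
    best hits, fragment-based average nucleotide identity (ANI), detection
    of genomic islands as GC-anomalous segments with mobile-genetic-element
    context, multi-evidence horizontal gene transfer inference combining
    composition, genomic context and gene-tree/species-tree incongruence,
    log-odds profile search for marker protein families, and
    genotype-phenotype trait concordance. A synthetic clade generator with
    planted ground truth (known pangenome structure, calibrated divergence,
    low-GC islands) makes every analysis stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'ani.R'
    'islands.R'
    'methods-show.R'
    'microevo-package.R'
    'orthology.R'
    'phylo.R'
    'traits.R'
    'profile.R'
    'simulate.R'
    'pipeline.R'
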