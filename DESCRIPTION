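Package: darkbin
Title: Conservative Taxonomy Assignment, GC-Coverage Binning and
    Novel-Taxon Discovery for Skin Metagenome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the assembly-based reconstruction of microbial
    genomes from shotgun skin metagenomes: conservative per-contig species
    assignment from alignment breadth and identity, preliminary K-means
    binning of unassigned ("dark matter") contigs on GC content and
    coverage with automated curation, fragment-based average nucleotide
    identity (ANI) novelty calls, core-genome concatenated phylogenies of
    curated bins, metagenomic multi-locus sequence typing (MLST) with a
    strain-identity rule, and a rarefaction-based diversity and paired
    contralateral-site comparison protocol. Includes seeded synthetic-cohort
    generators with machine-readable ground truth so the whole pipeline can
    be exercised and validated without access to raw metagenomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn,
    vegan,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
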