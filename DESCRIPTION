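Package: morffotools
Title: Molecular-Evolution Toolkit for Mobile ORFs in Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for characterising mobile open reading frames
    (MORFFOs) and canonical protein-coding genes in plastid genomes:
    sliding-window nucleotide diversity by codon position and pairwise
    Nei-Gojobori dN/dS with bootstrap confidence intervals, relative and
    absolute substitution-rate estimation by internode tip-to-root
    normalisation against a reference phylogram and chronogram, RNA-editing
    site classification from read-count pileups, relative synonymous codon
    usage (RSCU) with PCA ordination, a six-frame ORF scanner, and a seeded
    synthetic-data generator (codon-model sequence simulation, clock trees,
    pileups with planted edits) providing ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
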