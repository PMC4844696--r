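Package: volvocomp
Title: Comparative Genomics of the Transition to Multicellularity in Volvocine Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the comparative-genomics analyses used to
    study the origin of multicellularity in the volvocine green algae:
    phylostratigraphic gene-age assignment from taxonomy-annotated homology
    hits, rule-based classification of transcription-associated proteins from
    protein-domain hits, G-test screening of protein-domain abundance between
    unicellular and colonial lineages, symmetric and asymmetric Wagner
    parsimony and Dollo parsimony reconstruction of ancestral gene-family
    content on a rooted species tree, genome summary statistics from
    FASTA/GFF3, and scanning of retinoblastoma-family proteins for putative
    CDK phosphorylation sites. A synthetic-data generator with planted ground
    truth makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
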