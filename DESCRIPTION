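Package: sterolscan
Title: Survey of Bacterial Sterol Biosynthesis from Protein Sequences and
    Gene Complements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying sterol biosynthesis in bacteria from
    sequence data alone. Provides thresholded homolog screening of
    oxidosqualene cyclase (Osc) and downstream sterol-biosynthesis protein
    families against annotated references, classification of cyclases as
    lanosterol synthase (LAS) or cycloartenol synthase (CAS) from the
    diagnostic residue at human-Osc position 453 (with supporting positions
    381 and 449), a reaction-graph model of the sterol pathway that predicts
    the compounds an enzyme complement can produce from squalene,
    genotype-versus-lipid discrepancy analysis (orphan modifications and
    silent capacities), distance-based phylogenetics with outgroup rooting,
    and a synthetic-data generator producing divergent protein families,
    metagenome-like fragments, and strain cohorts with known ground truth.
    Ships machine-readable transcriptions of a published survey of
    Osc-containing bacterial genomes and their lipid profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Classification, Phylogenetics, Pathways
RoxygenNote: 7.3.3
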