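Package: metaprom
Title: Drug Off-Target Screening Against Human Microbiome Metaproteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens established drug target protein sequences against human
    microbiome metaproteome catalogues (gut, oral, vaginal) to flag potential
    pharmacological promiscuity. Provides an exact affine-gap pairwise
    alignment engine (Needleman-Wunsch and Smith-Waterman with Karlin-Altschul
    E-values), identity-threshold off-target calling, taxonomic and functional
    aggregation of hits (GTDB-style lineages, three-biome species overlap,
    pathogenicity classification), differential side-effect prevalence
    between microbiome-affecting and non-affecting drug targets, and a
    structural stage that classifies protein-ligand atomic contacts into
    element-pair classes, predicts binding affinity with a linear contact
    model, and compares binding-pocket residues through sequence alignment.
    A synthetic-data generator plants known homologs, species overlap
    structure, symptom enrichments and pocket edits so that every stage has
    a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
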