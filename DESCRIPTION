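Package: mycogeo
Title: Biogeography of Island Fungal Metabarcoding Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the biogeographic analysis of fungal
    ITS2 metabarcoding data from isolated island systems: greedy centroid
    clustering of amplicon sequence variants (ASVs) into operational
    taxonomic units (OTUs) at a fixed identity threshold, rank-abundance
    quartiles and order-level evenness, plant-associated taxon selection,
    known/unknown calls against reference sequence pools, latitudinal
    biogeographic classification, per-OTU haplotype networks with
    island-private haplotype detection, grid-based discovery of areas of
    endemism with spatial congruence scores, and variance partitioning of
    global abundance into environmental and spatial (Moran eigenvector)
    fractions. A seeded synthetic-data generator emulates the island
    dataset, the reference pools and the global occurrence table so every
    stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    geosphere,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    lme4,
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
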