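Package: micronetgwas
Title: Network Mapping of Host Genetic Control over Root-Microbiome Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pairwise microbe-microbe interactions (mutualism, antagonism,
    aggression, altruism) from host-by-OTU abundance tables using behavioral-ecology
    descriptors, builds per-host interaction networks, summarizes each network by six
    emergent indices (connectivity, closeness, betweenness, eccentricity,
    eigencentrality, PageRank) treated as quantitative phenotypes, maps them to host
    SNPs by single-marker linear association with MAF filtering and genomic-control
    diagnostics, and reconstructs directed acyclic QTL networks over significant SNPs
    by score-based Bayesian-network learning. Includes a synthetic-data generator with
    planted SNP effects for end-to-end validation, hub-taxon and hub-QTL detection,
    and GraphML/TSV export of all artifacts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
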