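Package: matrikin
Title: Kinship, Uniparental Diversity and Residence-Pattern Inference from
    Identity-by-Descent Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring post-marital residence patterns (matrilocality,
    patrilocality) in archaeological communities from genomic data. Turns
    refinedIBD-style identity-by-descent segment tables into pairwise kinship
    coefficients, relationship degrees and degree-weighted relatedness scores;
    computes mitochondrial and Y-chromosome haplotype diversity per burial site
    with first-degree pruning and a diversity-versus-relatedness screen;
    estimates the minimum number of female births behind a dominant matriline
    from its de novo mutation count; simulates sex-biased migration between
    demes with rejection-style inference of male and female migration rates;
    gene-drops genomes through simulated multi-generation pedigrees under
    matrilocal, patrilocal or mixed residence rules and classifies observed
    kinship distributions by regime; and builds weighted inter-site IBD graphs
    with consensus Leiden community detection summarised by a maximum
    clade-credibility tree. A synthetic-data module generates pedigrees,
    haplotype labels and IBD segment tables with the structure the analyses
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
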