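Package: gusome
Title: Structure-Guided Discovery and Quantification of Gut Microbial
    Beta-Glucuronidases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline for profiling the gut microbial
    beta-glucuronidase (GUS) complement ("GUSome") from metagenomic protein
    catalogs and read counts: structure-guided screening of candidate GUS
    genes by pairwise alignment to representative enzymes and conservation
    of seven catalytic residues, greedy redundancy clustering, structural
    class and taxonomy assignment, gene-length-bias-corrected abundance
    normalization, community diversity statistics, activity-based-probe
    metaproteomics quantification (unique-peptide protein intensities and
    sequence coverage), mycophenolate-glucuronide reactivation rate fitting
    from time courses, and Wald slope association of rates with GUS class
    abundance. Includes a fully labelled synthetic-cohort generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
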