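Package: estkit
Title: Simulation, Cleaning, Assembly and Comparative Analysis of Sanger EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for expressed sequence tag (EST)
    projects of the classic Sanger era: sliding-window quality clipping,
    vector and poly(A)/poly(T) boundary masking, stringent greedy
    overlap-layout-consensus assembly into unigenes, homology-guided and
    ab initio coding-sequence annotation with completeness classification,
    GC/GC3 and codon-usage statistics including correspondence analysis
    and optimal-codon detection, expression versus GC3 model fitting,
    amino-acid composition and hydrophobicity profiles across taxa,
    protein-interaction sub-network extraction with consistency scoring
    and fusion, pathway coverage summaries, and taxonomic-specificity
    classification of homology hit profiles.  A seeded synthetic-data
    generator emulates every input (quality-decaying reads, vector
    contamination, poly(A) tails, expression-dependent GC3, modular
    scored interactomes, taxon-labelled hit tables) so the whole pipeline
    is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    igraph,
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
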