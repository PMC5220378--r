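Package: parcubin
Title: Genome Bin Refinement and Comparative Genomics for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating genome bins recovered from metagenomes and for
    comparing the resulting genomes. Builds tetranucleotide-composition and
    time-series abundance feature spaces over 5 kb scaffold windows, trains an
    emergent self-organizing map (batch SOM, PCA codebook initialization,
    toroidal topology) to validate a bin and recruit additional scaffolds via a
    percentile distance threshold, estimates completeness from a universal
    single-copy marker inventory, and computes reciprocal-best-hit orthology
    with exact Smith-Waterman alignment, average amino-acid identity (AAI) and
    ortholog-fraction matrices. A seeded synthetic-community and
    synthetic-proteome generator provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
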