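Package: stratiprof
Title: Depth-Resolved Metagenomic Profiling of Stratified Water Columns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for depth-resolved analysis of marine photic-zone
    metagenomes sampled across stratified and mixed water columns.
    Implements read recruitment to reference genomes with identity and
    alignment-length filters, the RPKG abundance statistic (reads per
    kilobase of genome per gigabase of metagenome) with a presence
    threshold, classification of genomes into stenobathic, intermediate
    and eurybathic depth ranges and into seasonal-occupancy categories,
    16S rRNA fragment detection and taxonomic profiling with Simpson
    diversity, whole-metagenome reciprocal read similarity with
    hierarchical clustering, composition-based contig binning
    (tetranucleotide frequencies, GC, coverage) with single-copy marker
    completeness and contamination estimates, rhodopsin detection with
    blue/green spectral-tuning classification and recA/radA-normalised
    abundance, glycoside-hydrolase rate statistics, and small
    environmental computations (N:P ratio, flow-cytometry counts).
    A seeded synthetic stratified-community generator with full ground
    truth supports testing and benchmarking of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
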