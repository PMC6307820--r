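Package: panxo
Title: Fine-Scale Meiotic Crossover Hotspot Mapping on Panmolecule Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fine-scale mapping of meiotic crossover hotspots from
    pollen-typing experiments. Builds a "panmolecule" union coordinate system
    from two parental haplotypes of an amplicon with bidirectional liftover and
    polymorphism annotation, estimates crossover and parental molecule
    concentrations from limiting-dilution titration series (Poisson zero-class
    estimator) to obtain genetic distance (cM) and recombination rate (cM/Mb),
    calls crossover breakpoint intervals from per-molecule allele calls,
    classifies crossover read pairs from deep sequencing of mass-amplified
    crossover molecules via an exact-match dual-template filter cascade, and
    models the negative non-linear relationship between interhomolog
    polymorphism and crossover frequency in adjacent windows. Includes a fully
    seeded synthetic-data generator for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
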