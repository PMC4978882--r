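Package: ldhotscan
Title: Composite-Likelihood Detection of Recombination Hotspots from
    Patterns of Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Detects recombination hotspots in phased SNP data from patterns
    of linkage disequilibrium, using a composite likelihood ratio test built
    on Monte Carlo two-locus sampling probabilities.  P-values are calibrated
    against a lookup table of constant-rate coalescent simulations,
    conditioning on the observed number of segregating sites and the
    estimated background recombination rate.  Implements three published
    hotspot-calling protocols, a coalescent simulator with recombination
    maps (including a per-lineage ancestral recombination graph and a
    two-locus genealogy sampler), and a simulation framework for measuring
    base-pair-level power, false positive rate and false discovery rate of
    hotspot callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
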