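Package: lonscreen
Title: Multi-Criteria Quantitative Proteomics Screen for Lon Protease Substrates
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reusable pipeline for identifying candidate
    substrates of the Lon protease from isobaric-label (TMT10) quantitative
    proteomics in Caulobacter crescentus. Protein abundances measured across
    ten strain/condition channels in two biological replicates are converted
    to condition ratios, averaged over replicates with a single-replicate
    fallback, thresholded against four substrate criteria (elevated steady
    state without Lon, up on Lon depletion, down on lon overexpression,
    stabilized after translation shut-off), and combined by a
    k-of-four rule with full Venn/set accounting. Companion modules provide
    translation shut-off chase half-life estimation by log-linear fitting,
    functional-category tallies, a synthetic-data generator with planted
    substrate classes, and recovery metrics for evaluating the screen's
    operating characteristics against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Proteomics, Software, MassSpectrometry
Config/testthat/edition: 3
RoxygenNote: 7.3.3
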