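Package: phenoflux
Title: Multispectral Single-Turnover Chlorophyll Fluorescence Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits single-turnover chlorophyll-a fluorescence
    induction and relaxation transients acquired under a multispectral variable
    actinic light protocol, assembles the resulting per-sample photophysiology
    metric cube (quantum yield, functional absorption cross-section, excitonic
    connectivity, non-photochemical and photochemical quenching, antenna-bed
    quenching, and reoxidation time constants), clusters samples into
    light-response phenotypes with multiscale bootstrap support, normalizes ITS2
    symbiont type counts by genus rDNA copy number, compares metric trajectories
    and cellular traits across phenotypes, and correlates photophysiological
    metrics with cellular traits in a thresholded signed network. Includes a
    synthetic cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lme4,
    lmerTest,
    multcomp,
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
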