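Package: eggchamber
Title: Phase-Field Simulation and Morphometric Analysis of Egg Chamber
    Self-Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how differential soma-germline affinity drives
    tissue self-organization during Drosophila oogenesis. The package
    generates synthetic egg-chamber cohorts with the statistical structure
    of confocal medial-section data, computes a 24-parameter morphometric
    description with phase assignment by germline area, embeds cohorts
    along the developmental trajectory (PCA + UMAP) and detects genotype
    divergence, implements the genotype-comparison regression and
    critical-size ANOVA procedures, and provides two phase-field models:
    a multicellular model of follicle-cell redistribution over an
    affine/non-affine germline boundary, and a two-phase oocyte/nurse-cell
    model with a signed, Eya-derived boundary affinity field read out via
    the interface contact angle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    uwot,
    igraph,
    emmeans,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
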