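Package: lowbiome
Title: Low-Biomass Tissue Microbiome Analysis with Reproducible Power Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for low-biomass tissue microbiome studies built
    around taxonomic read counts (Kraken-style reports and genus/phylum count
    tables). Implements curated-list decontamination with a human-associated
    species rescue rule and recursive upward propagation of genus-level
    removals through the taxonomy; rarefaction-based richness, Shannon alpha
    diversity, Bray-Curtis beta diversity and marginal-term PERMANOVA;
    centered log-ratio (CLR) paired tumor-normal differential abundance;
    per-taxon stratified Cox proportional-hazards survival scans; fixed-effect
    meta-analysis with Fisher's combined probability test; a
    normal-approximation paired-test power framework with
    minimum-detectable-effect solving and a simulation-based Cox power
    framework with log-normal baseline hazards; and a synthetic multi-platform
    cohort generator with known ground truth so the whole pipeline, including
    its power calibration, is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
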