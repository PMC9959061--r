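Package: stazr
Title: Steatosis Scoring and Membrane-Order Mapping for Zebrafish Liver
    Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies hepatic lipid accumulation in zebrafish larvae from
    two-channel confocal fluorescence images. Computes a composite steatosis
    score per larva from the control-corrected green/blue fluorescence ratio,
    lipid-droplet density and droplet area fraction inside a user-supplied
    liver region of interest; maps membrane lipid order via per-pixel
    generalized polarization (GP) from ordered/disordered channel pairs with
    per-batch control anchoring (delta-GP); summarises treatment groups
    (mean, SEM, n) and runs the assay's comparison tests versus control
    (Kruskal-Wallis with Dunn's post-test, one-way ANOVA with Dunnett's
    post-test, two-way ANOVA with Bonferroni contrasts). A seeded synthetic
    image generator produces larvae, cohorts and GP channel pairs with known
    ground truth so the whole pipeline is testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    multcomp,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
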