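Package: crowdquant
Title: Quantification of Cell-Crowding Mechanotransduction Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and signal-analysis toolkit for studies of cell-crowding
    mechanotransduction in breast epithelial cells. Quantifies invasive cell
    fractions from fluorescent-gelatin degradation assays, partitions a
    protein channel into plasma-membrane/cytosol/nucleus compartments from
    three-channel line profiles, extracts treatment-locked calcium transients
    (delta-Ca) from Fluo-4 time series, estimates single-cell diffusivity and
    directional speed from nucleus trajectories via mean-squared-displacement
    fits, fits the Hertz spherical contact model to nanoindentation curves,
    measures cell volume from confocal z-stacks, and provides the study-level
    statistical layer (fold-change enrichment, two-rater diagnostic
    concordance with binomial confidence intervals, Mann-Whitney tests,
    scaling relations). A synthetic-data module generates every input
    modality with known ground truth so the full pipeline is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
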