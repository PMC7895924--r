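Package: mosaictile
Title: Quantitative Analysis of Mosaic Gene Deletion in Epithelial Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying non-cell-autonomous effects of mosaic gene
    deletion in epithelial monolayers, motivated by planar cell polarity
    disruption in the mouse neuroepithelium. Classifies mosaic cells from
    membrane-reporter fluorescence by a pixel-fraction threshold rule, builds
    apical neighbour graphs from dilated label masks, quantifies Lewis'-law
    statistics and neighbour-sharing amplification with a closed-form lattice
    model, aligns and compares pulsatile apical-constriction time series,
    analyses laser-ablation retraction with the embryo as the unit of measure,
    and quantifies border-class and cap-versus-cortical intensity patterns.
    A fully seeded synthetic-epithelium generator (Voronoi and hexagonal
    tessellations, fluorescence renders, area-trace dynamics, ablation and
    embryo cohorts) provides ground truth so the whole pipeline can be
    validated without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    deldir,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
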