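Package: palaeoniche
Title: Thermal Niche-Environment Interaction Modelling of Phanerozoic
    Marine Biodiversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates global marine biodiversity from gridded monthly
    sea-surface temperature fields using a pool of randomly generated
    rectangular thermal niches. Species richness emerges from the
    interaction between each niche and the local monthly temperature
    regime on shallow shelves around continents; allopatric speciation is
    represented by counting isolated patches of each niche's annual
    occupancy. The package provides a synthetic palaeo-world generator
    (drifting and fragmenting continents, latitudinal temperature
    gradients, anti-phased seasonal cycles), shelf-mask construction with
    ring-width and bathymetry variants, WGS-84 cell areas, latitudinal
    biodiversity gradients, continental indices, a composite fossil
    species richness index built by principal component analysis of
    multiple diversity curves, and Pearson correlations with
    autocorrelation-corrected significance (effective degrees of
    freedom) and minimal-df diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
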