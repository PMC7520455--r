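Package: plumacolor
Title: Avian Plumage Color Spaces, Complementary Colors and Phylogenetic Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for avian plumage coloration measured by
    UV-visible reflectance spectrometry. Computes cone quantum catches under
    averaged ultraviolet-sensitive (UVS) and violet-sensitive (VS) avian visual
    systems with von Kries correction, maps patches into Goldsmith's tetrahedral
    color space with convex-hull volume occupancy, transforms catches into a
    receptor-noise-limited XYZ space in which Euclidean distance is measured in
    just-noticeable differences, extracts a one-dimensional elevation "color
    score" from spherical coordinates, tests for complementary colors on
    opposite sides of the achromatic point, and quantifies phylogenetic signal
    (Pagel's lambda with randomization, Mantel matrix correlations) in
    region-wise color and luminance scores. Includes a synthetic-data generator
    (template reflectance spectra, Yule trees, lambda-scaled Brownian traits)
    so the whole pipeline is testable without museum spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools
Config/testthat/edition: 3
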