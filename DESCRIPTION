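Package: grainmorph
Title: Morphometric, Fractal and Texture Characterization of Grain
    Cross-Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image-analysis pipeline for transverse cross-sections of
    cereal grains, developed around rice endosperm maturation series.
    Binarizes calibrated grayscale micrographs, extracts the grain
    region, and computes calibrated shape descriptors (area, perimeter,
    Feret lengths, shape factor, elliptic factor, compactness factor),
    log-ratio fractal dimensions of perimeter and area with ensemble
    power-law exponents, and gray-level co-occurrence matrix texture
    statistics (entropy, angular second moment). Group comparisons
    across maturation stages and panicle positions use Kruskal-Wallis
    gating with Dunn's rank-based post-hoc test and compact letter
    displays. Includes a synthetic grain-image generator with
    controllable size, ellipticity, boundary roughness and texture
    organization so the full pipeline is testable without micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
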