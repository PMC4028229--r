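Package: epiOCT
Title: Corneal Epithelial Thickness Profiling from Anterior-Segment OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for measuring corneal epithelial thickness
    profiles from long-scan-depth spectral-domain OCT B-scans of the horizontal
    and vertical meridians. Includes a physically forward-modelled digital
    corneal phantom (curved anterior surface, thin epithelial layer thickening
    toward the limbus, Snell-refracted back-boundary distortion, speckle noise
    with depth-dependent sensitivity roll-off, superior eyelid occlusion),
    sub-pixel two-interface boundary segmentation by dynamic programming,
    refraction (Snell's law) dewarping of the back boundary with a group index
    of 1.389, perpendicular thickness profiling on a 0.5-mm lateral grid with
    left-eye mirroring and zonal summaries, and test-retest repeatability
    statistics (coefficient of repeatability, ICC(2,1), paired t) per grid
    location and per zone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
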