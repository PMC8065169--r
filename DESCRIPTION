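Package: deltamaps
Title: Connectivity-Based Ocean Ecoregionalization from Gridded Anomaly Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies spatially contiguous, functionally homogeneous regions
    (domains) in gridded monthly sea-surface-temperature anomaly fields and
    infers the weighted, lagged functional network that connects them, in the
    spirit of the delta-MAPS family of climate-network methods. Domains are
    grown from cores of high local homogeneity and linked through lagged
    Pearson correlations whose significance is assessed with Bartlett's
    autocorrelation-corrected variance. Companion tools compute surface
    kinetic energy, detect kinetic-energy fronts by percentile thresholding
    and K-means segmentation, validate domain boundaries against fronts, and
    track ecoregion fragmentation across sliding multi-year time slots. A
    seeded synthetic-field generator with planted regions, lagged couplings
    and boundary-aligned jets supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
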