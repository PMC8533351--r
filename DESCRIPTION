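Package: cardiolum
Title: Aequorin Cardioluminescence Analysis for the Larval Zebrafish Heart
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for calcium imaging of the beating zebrafish
    larva heart with the bioluminescent GFP-aequorin reporter. Converts raw
    luminescence recordings into the aequorin photon budget (L, Ltotal,
    Lconsumed, Lmax) and the consumption-corrected, calcium-proportional
    L/Lmax signal; computes per-frame signal-to-noise ratios from background
    regions; detects beats and quantifies calcium transient kinetics
    (amplitude, 10-90% rise, 90-10% decay), heart rate and the
    atrio-ventricular rate ratio; derives ventricular hemodynamics
    (fractional shortening, fractional area change, ellipsoid volumes,
    stroke volume, cardiac output, ejection fraction) and group-level
    fold-change reports. Includes a seeded forward simulator of aequorin
    bioluminescence in a beating heart - calcium transients driving
    stochastic photon emission from a depleting photoprotein pool, camera
    background, rendered 16-bit image stacks, ventricle geometry, and
    GCaMP-style fluorescence - so every analysis stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    mgcv,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
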