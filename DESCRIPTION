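Package: ssaxs
Title: Spectral Small-Angle X-Ray Scattering Estimation of Brain Amyloid Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduction and analysis pipeline for spectral small-angle X-ray
    scattering (sSAXS) measurements of amyloid burden in the rodent brain,
    together with a forward simulator of the polychromatic instrument and a
    synthetic fluorescence-histology reference standard. Converts 3D
    photon-counting detector stacks (pixel x pixel x 1-keV energy bin) to
    momentum-transfer profiles S(q) via transmission correction, per-energy
    q binning and energy summation; quantifies the cross-beta amyloid
    signature as the area under the 6 nm^-1 Bragg peak (AUP, 3.6-8.4 nm^-1)
    and the wild-type-normalized excess Delta-AUP; and correlates burden
    estimates with Thioflavin-S percent-area amyloid load.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
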