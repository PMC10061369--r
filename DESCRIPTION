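Package: dropsol
Title: Droplet-Microfluidic Protein Solubility Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for droplet-microfluidic PEG-precipitation
    solubility screens. Simulates multi-channel fluorescence images of
    water-in-oil droplets with known composition gradients and aggregation
    ground truth, detects droplets and extracts per-channel intensity
    statistics, applies three-part intensity calibration (dark frame,
    flat field, endpoint gain) to infer droplet compositions, classifies
    droplets as mixed or aggregate-containing from intra-droplet intensity
    inhomogeneity, fits support-vector-machine phase boundaries with
    Platt-calibrated aggregation probabilities and bootstrap uncertainty,
    and derives formulation analytics: relative solubility, per-additive
    solubility slopes (including two-regime salt behaviour), two-excipient
    combination slopes, area-under-curve excipient comparison, and
    condition ranking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
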