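Package: nirquant
Title: Quantification of Planar Near-Infrared Fluorescence Images of Small Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying planar near-infrared (NIR) whole-body
    fluorescence images of tumor-bearing mice imaged with targeted contrast
    agents. Implements threshold-based region-of-interest (ROI) detection,
    hip-reference luminosity normalization, autofluorescence estimation from
    uninjected controls, near-ROI scattered-light background annuli, a
    normalized signal-to-noise statistic per organ and timepoint,
    biodistribution time-course tables, cumulative pixel histograms,
    white-field composite overlays, and an ex vivo lung melanoma-node
    localization index. Includes a synthetic mouse-phantom generator with
    known ground truth (uptake kinetics, scattering point-spread function,
    Poisson and read noise, per-subject luminosity and geometry variation)
    for validating every step of the quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'NIRImage-methods.R'
    'RegionSet-methods.R'
    'phantom.R'
    'lung.R'
    'io.R'
    'roi.R'
    'quantify.R'
    'report.R'
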