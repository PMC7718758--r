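Package: photomorbid
Title: Photomorbidity Dose-Effect Modeling and Light-Budget Planning for
    Long-Term Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and avoid photomorbidity (light-induced growth
    rate reduction) in long-term multi-color fluorescence time-lapse imaging of
    yeast microcolonies. Converts illumination settings into light doses with
    hardware-delay correction, estimates microcolony growth rates from cell
    count time series, fits sigmoidal light-dose/growth-rate curves by least
    absolute deviations and extracts ED50 and the no-observed-effect level
    (NOEL), calibrates fluorescence signal, background and noise against light
    dose to estimate and predict signal-to-noise ratios of fluorescent protein
    fusions, fits two-term exponential photobleaching decays, scores the
    interaction of excitation wavelengths with the coefficient of drug
    interaction, and plans multi-color imaging conditions under an additive
    photomorbidity model. Includes a synthetic-data generator emulating the
    full experimental design for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
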