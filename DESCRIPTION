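Package: wetrad
Title: Water-Equivalent Thickness Accuracy Analysis for Ion Radiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing the
    water-equivalent thickness (WET) accuracy of energy-painted helium-ion
    radiography against x-ray CT based stopping-power maps. Provides a
    procedural digital head phantom with tissue-surrogate materials,
    bias-model emulation of single- and dual-energy CT relative stopping
    power volumes, sagittal WET projection with external-air stripping and
    mutual-information rigid registration, a single-ion radiography
    simulator (Bragg-edge energy-deposition calibration curves, region-wise
    energy painting, event generation and median-based WET reconstruction),
    and the comparison machinery used in ion-imaging range-verification
    studies: relative WET difference maps, MAPE and RMSPE with subregion
    standard errors, local gamma analysis, distribution summaries, and
    material-abundance correlation of WET errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
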