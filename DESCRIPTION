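Package: sosdamage
Title: Radiation-Damage Diagnostics for Raster-Scanned Serial Crystallography
Version: 0.1.0
Authors@R:
    person("SOS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for assessing radiation damage in serial synchrotron and
    serial femtosecond crystallography data collected on unpatterned
    (sheet-on-sheet) fixed targets. Models the serpentine raster-scan exposure
    geometry and the time-distance structure between exposures, estimates
    damage spread and multiple-hit fractions, performs Monte-Carlo merging of
    snapshot reflection lists, fits Wilson B factors from observed and
    calculated intensities, clusters unit-cell populations, and quantifies
    uncertainty on refined heme-site geometry by bootstrap resampling of
    images through a miniature structure-factor refinement engine. A
    synthetic snapshot-diffraction generator with known ground truth supports
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
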