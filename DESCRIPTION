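Package: airwayflow
Title: Endoscopic OCT Airway Reconstruction and Lattice-Boltzmann Airflow
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale computational pipeline for localizing upper-airway
    obstruction in obstructive sleep apnea from endoscopic optical coherence
    tomography (OCT) catheter pullbacks. Generates synthetic rotational polar
    B-scan stacks of an airway lumen with paired awake/asleep states,
    preprocesses and segments the lumen wall, lofts the contours along the
    tracked catheter path into a watertight 3D airway surface, simulates
    airflow through the reconstructed lumen with a D3Q19 lattice-Boltzmann
    solver (SRT and MRT collision operators), and ranks obstruction sites by
    the second axial derivative of the cross-section-averaged pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
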