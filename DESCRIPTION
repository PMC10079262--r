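Package: trackmotility
Title: Quality Control, Motility Statistics and Random-Walk Modelling of Cell Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing 2D and 3D cell trajectories from time-lapse
    microscopy. Provides a dedicated tracks data structure with delimited-text
    import/export, decomposition of tracks into subtracks for cell-based,
    step-based and staggered analyses, a catalogue of motility measures
    (displacement, speed, straightness, turning angles, asphericity and
    others), mean squared displacement and autocorrelation curves, quality
    control for tracking artifacts (double tracking, gaps, global drift),
    Hotelling's T-squared test for subtle directional bias in step
    displacements, per-track feature matrices with PCA/MDS embedding and
    clustering, and simulation of cell migration under Brownian, bootstrap
    and Beauchemin-type random walks, including least-squares fitting of
    random-walk models to empirical mean squared displacement curves.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
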