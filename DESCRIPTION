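Package: pearscc
Title: Stone Cell Content Evaluation of Pears from Vis/NIR Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometrics pipeline for estimating the stone cell content (SCC,
    percent by mass) of pear pulp from visible/near-infrared diffuse
    reflectance spectra. Provides spectra containers and delimited-text I/O,
    SNV, MSC and Savitzky-Golay preprocessing with a PLSR-based comparison,
    SPXY calibration/validation partitioning, characteristic-wavelength
    selection by the successive projections algorithm (SPA) and Monte-Carlo
    uninformative variable elimination (MCUVE), SIMPLS partial least squares
    regression, and RBF-kernel support vector regression tuned by particle
    swarm optimization. A configurable synthetic spectra generator with known
    ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
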