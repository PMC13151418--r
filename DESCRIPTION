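Package: nirsblock
Title: Simulation and Block-Design Analysis of Infant fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing block-design functional
    near-infrared spectroscopy (fNIRS) experiments of the kind used to study
    auditory processing in infants. Provides a forward simulator for
    dual-wavelength raw intensity recordings with known ground-truth
    hemodynamic effects, a HOMER-style preprocessing cascade (channel pruning,
    optical-density conversion, motion-artifact detection, spline and wavelet
    correction, band-pass filtering, modified Beer-Lambert conversion to
    hemoglobin concentration), block averaging with per-block and
    per-participant exclusion rules, and channel-wise t-tests with
    family-wise error control by max-|t| permutation null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
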