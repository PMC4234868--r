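Package: pedicleNIRS
Title: Detection Depth and Alarm Thresholds for a Dual-Fiber NIRS Pedicle
    Screw Probe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for determining the detection depth of a small-separation
    dual-fiber near-infrared reflectance probe advanced through layered bone,
    and for deriving an alarm threshold for pedicle screw insertion. Provides
    a photon Monte Carlo simulator for layered slabs (Henyey-Greenstein
    scattering, weighted photon packets, Russian roulette), a detection-depth
    statistic based on a two-standard-deviation deviation onset rule, spectral
    pattern factors (area, peak, slope) of diffuse reflectance spectra,
    ratio-based selection of the most discriminating pattern factor with an
    alarm band, and a synthetic-data generator emulating two-layer phantom and
    porcine vertebra measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    pracma,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
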