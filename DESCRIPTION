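Package: accelbcg
Title: Ballistocardiographic Heart-Beat Detection from Bio-Logging
    Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual heart beats and instantaneous heart rate in
    tri-axial accelerometer records from animal-borne tags by constructing a
    ballistocardiogram (BCG): band-pass filtering, Savitzky-Golay
    differencing, Shannon-entropy fusion of one or three axes, and triangular
    moving-average smoothing. Candidate peaks are separated into heart beats
    and residual noise by clustering in height-prominence space. Includes
    dive segmentation from depth, motionless-period detection from gyroscope
    rotational velocity, validation statistics (ordinary-least-squares
    equivalence against ECG-derived heart rate, band-integrated spectral
    signal-to-noise ratio, robust Theil-Sen regression of heart rate on
    normalized dive time), and a seeded simulator of tag records with
    ground-truth beat times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
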