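Package: ecgforge
Title: Synthetic 12-Lead ECG Simulation with Wave Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based simulator for 12-lead electrocardiogram (ECG)
    signals with aligned per-sample wave-class segmentation masks (P wave, P-R
    interval, QRS complex, ST segment, T wave, T-P segment and T/P overlap),
    covering sinus rhythm and atrial fibrillation and six morphological
    phenotypes. Simulated or imported signals can be rendered into standard
    calibrated ECG paper images with pixel-aligned segmentation masks,
    degraded with synthetic artefact, and read back from masks into label
    sequences and millivolt signals via grid-calibration search. A rule-based
    atrial fibrillation detector operates on segmentation label sequences
    (QRS cluster detection, R-R dispersion, pre-QRS P-wave search, brute-force
    threshold fitting), with classification and segmentation-overlap metrics
    and deterministic stratified dataset splitting for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
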