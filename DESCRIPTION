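Package: embidetect
Title: Two-Stage Automated Swallow Detection from Combined EMG and
    Bioimpedance Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pharyngeal swallows in synchronized submental surface
    electromyography (EMG) and cervical bioimpedance (BI) recordings. Stage
    one finds EMG activity bursts with a double-threshold detector and BI
    valleys by piecewise linear approximation, and pairs them under the
    physiological rule that muscle activity precedes the drop in
    bioimpedance during laryngeal elevation. Stage two classifies the
    paired candidates as swallow or nonswallow with a support vector
    machine trained on swallowing-related parameters (maximum and speed of
    laryngeal elevation, preparation time, closure duration). Includes a
    calibrated synthetic EMG/BI recording generator with ground-truth
    annotations, contingency-table evaluation, Mann-Whitney group
    comparison, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    e1071,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
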