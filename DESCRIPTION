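Package: raetrace
Title: Recursive Auto-Encoders for Abnormal Behaviour Detection in Smart-Home Sensor Streams
Version: 0.1.0
Authors@R:
    person("raetrace", "developers", email = "raetrace@example.org", role = c("aut", "cre"))
Description: Detects dementia-related abnormal behaviour in ambient smart-home
    binary sensor event streams. Provides a reader/writer for CASAS-style
    event logs, a synthetic single-resident routine simulator with
    activity-level and sub-activity-level anomaly injection, bag-of-sensors
    (BOS) and raw-sensor-measurement (RSM) window features, linear and greedy
    recursive auto-encoders trained by backpropagation through structure
    (unsupervised or semi-supervised), reconstruction-error anomaly scoring,
    ROC/AUC and macro classification metrics, and n-gram sub-activity pattern
    mining from learned merge trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
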