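Package: hertools
Title: Heartbeat-Evoked Response Analysis with Cluster-Based Permutation Inference
Version: 0.1.0
Authors@R: person("Analysis", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse heartbeat-evoked responses (HERs) in
    intracranial or scalp electrophysiology. Detects ECG R-peaks by
    template matching, extracts heartbeat-locked epochs preceding each
    stimulus, correlates single-trial HER amplitude with continuous
    behavioural ratings, and assesses significance with cluster-based
    permutation tests, a surrogate-heartbeat control, and a group-level
    median-split cluster t-test. Includes a synthetic-session simulator
    with known ground-truth heartbeat/rating coupling so that every
    stage of the pipeline can be validated without patient data, plus
    EDF and TSV readers/writers and a subcommand-style pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
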