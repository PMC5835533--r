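Package: ieptask
Title: Task-Modulation Analysis of Intracranial Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and statistical analysis of trial-level intracranial
    evoked potentials (iEPs) recorded from depth electrodes during
    self-projection tasks. Provides a synthetic epoch generator with
    region-specific early and late condition effects, epoch preprocessing
    (zero-phase Butterworth band-pass filtering, robust artifact rejection,
    condition collapsing, evoked averaging), window-integral task-modulation
    features, linear support-vector classification of electrodes with
    leave-one-out cross-validation and exhaustive label-permutation
    significance testing, cluster-based permutation statistics on
    single-trial amplitudes, and an electrode-subset power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
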