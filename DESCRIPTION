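Package: ratafib
Title: Simulation and Analysis of Atrial Fibrillation Burden in Rodent Telemetry ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the analysis chain of rodent atrial-pacing studies of
    atrial fibrillation (AF): generation of annotated synthetic rat ECG and
    beat-time recordings with autonomic modulation, atrial premature beats and
    AF episodes; QRS detection and P-wave assessment on rendered waveforms;
    rule-based rhythm classification with episode segmentation, 24-h burden
    and pacing-inducibility metrics; heart-rate-variability analysis with
    rat-specific spectral bands (time domain SDNN, RMSSD, pNN5; frequency
    domain LF, HF, LF/HF via Lomb-Scargle on the uneven beat time base);
    normality-gated two-group and repeated-measures statistics; and
    housekeeping-normalized gene-expression comparison. A config-driven
    pipeline reproduces the full study-report surface from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
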