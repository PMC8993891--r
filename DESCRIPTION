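Package: hfbseq
Title: Single-Trial High-Frequency Broadband Activation Analysis for
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for electrocorticography (ECoG) studies of
    task-evoked neuronal population activity. Transforms continuous
    multichannel voltage recordings into baseline-corrected high-frequency
    broadband (HFB, 70-180 Hz) power epochs via Morlet wavelet
    decomposition, detects single-trial activations with a sliding-window
    test under Benjamini-Yekutieli false-discovery-rate control and a
    50-ms persistence rule, extracts per-trial latency and power metrics,
    classifies electrode sites by functional specificity and self/other
    selectivity, and fits mixed-effects models of region-of-interest
    activation latencies and behavior. Includes a ground-truthed synthetic
    iEEG session generator (pink-noise background, line noise, calibrated
    band-limited bursts, coupled response times and choices) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
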