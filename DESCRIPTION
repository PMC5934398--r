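Package: betaflow
Title: Directed Beta-Band Synchrony from Short Multi-Trial LFP Epochs
Version: 0.1.0
Authors@R: person("betaflow developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates beta-band spectral Granger causality between lower
    (V1/V2-like) and higher (V4/TEO-like) cortical populations from very
    short multi-trial local field potential epochs using pooled multi-trial
    autoregressive modelling. Provides bootstrap inference for directional
    asymmetry with omnibus family-wise correction, 1/f aperiodic background
    removal by robust regression, spectral-peak detection with a
    trial-shuffle permutation null, a time-reversal control against
    common-input artifacts, and decoding of a two-level behavioural context
    from spatial patterns of top-down beta-peak causality with a linear
    support vector machine validated by delete-d jackknife resampling. A
    ground-truth vector-autoregressive simulator of oscillatory LFP
    ensembles makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
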