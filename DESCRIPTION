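Package: emgadapt
Title: Adaptive Time-Windowing for Surface EMG Pattern Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Confidence-thresholded adaptive window sizing for surface
    electromyogram (sEMG) pattern-recognition control. Classifies overlapped
    analysis windows with a probabilistic linear discriminant classifier on
    spectral-regression-reduced features (time-domain, wavelet-packet energy,
    or time-domain power-spectral descriptors) and grows the window from
    150 ms up to 350 ms whenever the largest class posterior falls below a
    subject-specific confidence threshold, rejecting the decision if the
    maximal window is reached without sufficient confidence. Includes a
    synthetic multi-channel EMG generator, threshold tuning by
    error/extension trade-off curves, and majority-vote and Bayesian-fusion
    post-processing baselines.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
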