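Package: oscistim
Title: State-Dependent Modulation of Cortical Alpha Oscillations by
    Periodic Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward models and analysis tools for studying how 10 Hz
    periodic direct cortical stimulation interacts with endogenous alpha
    oscillations as a function of behavioral state (eyes closed, eyes
    open, task engaged).  Implements a static threshold-summation model
    of phase-gated stimulation responses, a delayed-feedback
    excitatory-inhibitory neural oscillator network integrated with an
    Euler-Maruyama scheme, template-matching removal of stimulation
    artifacts from electrocorticography (ECoG) recordings, Morlet-wavelet
    power spectra on a dual-resolution frequency grid, and
    modulation-index statistics, together with a seeded synthetic-ECoG
    generator so the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
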