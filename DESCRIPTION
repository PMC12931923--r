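Package: locuswm
Title: Generative Models of Transsaccadic Spatial Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares seven generative models of location-recall error
    in a continuous-report spatial working-memory task with controlled saccade
    demands (the LOCUS paradigm). Models range from a single allocentric
    representation to dual eye-centred (retinotopic) representations with
    fixation-memory decay, noisy saccade-vector updating, and interference from
    the unprobed item. Inference is by Laplace-approximation (variational
    Laplace) Bayesian inversion with a damped Newton scheme, giving posterior
    parameter densities and an approximate log model evidence per subject.
    Includes fixed-effects Bayesian model selection, model and parameter
    recovery analysis, parametric-empirical-Bayes group contrasts, a Bayesian
    score regression on posterior parameter estimates, a synthetic session and
    gaze generator, and eye-tracking compliance classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
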