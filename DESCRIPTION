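Package: adaptddm
Title: Sensory and Decisional Components of Perceptual Adaptation via
    Drift-Diffusion Modelling
Version: 0.1.0
Authors@R:
    person("adaptddm", "maintainers", email = "adaptddm@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-alternative perceptual adaptation
    experiments that record both choices and response times. Fits logistic
    psychometric functions (point of subjective equality, slope changes),
    fits drift-diffusion models by two strategies (closed-form choice
    probability and mean response time, and full joint choice/response-time
    likelihood via a Crank-Nicolson Fokker-Planck solver with absorbing
    bounds), computes bootstrap standard errors and across-subject
    aggregate p values, and partitions adaptation-induced shifts of the
    psychometric function into sensitivity (drift-rate), decision-bound,
    and interaction contributions. Includes a calibrated trial simulator
    for multi-subject, multi-condition experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
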