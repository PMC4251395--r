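Package: effectmodel
Title: Effect-Model Analysis of Treatment Benefit on the L'Abbe Plane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating and simulating the effect model: the
    relationship between the risk of a clinical event without treatment (Rc)
    and with treatment (Rt) for one disease/event/treatment triplet. Fits
    the linear effect model Rt = a*Rc + b to randomized-trial summary data
    by weighted least squares, derives the natural decision threshold
    s = b/(1-a), and runs sensitivity and polynomial model-comparison
    checks. A mechanistic route samples virtual patient populations,
    pushes each subject through a one-compartment PK, Hill stimulus,
    transduction/feedback and logistic-risk chain to obtain per-subject
    (Rc, Rt), absolute benefit, number of prevented events with bootstrap
    prediction intervals, and the shape of the resulting effect model.
    Decision utilities cover number needed to treat, per-patient treatment
    comparison, natural-threshold rules and budget-constrained allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
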