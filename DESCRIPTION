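Package: combcoherence
Title: Coherence of Model-Based Dose-Finding Designs for Drug Combination Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coherence of model-based phase I
    dose-finding designs for two-agent drug combinations. Implements the
    published dose-toxicity surfaces used by combination designs (four-parameter
    logistic, generalized CRM, scaled logistic, change-point, Clayton and Gumbel
    copula-type, log-linear, and six-parameter models) with their partial-order
    parameter constraints; reproducible posterior-mean estimation under
    constrained priors via deterministic quadrature or seeded importance
    sampling; trial engines for designs that forbid (ND) or allow (D) diagonal
    dose moves and for two-stage titration designs; and an auditing layer that
    classifies every dose transition against the definition of coherence under
    weak (model-estimate) and strong (true-probability) semantics and
    empirically checks the sufficient conditions (sign condition on posterior
    updates, uniform monotonicity, diagonal order agreement, and the two-stage
    switch condition) on simulated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
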