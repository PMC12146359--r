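Package: violdyn
Title: Compartmental Dynamics of Gender-Segregated Violence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling gender-segregated violence with a four-compartment
    system of ordinary differential equations (aggressors, susceptibles, male and
    female victims). Provides the base dynamics with logistic aggressor growth and
    mass-action victimization, two intervention extensions in which female victims
    and aggressors return to the susceptible class, closed-form and numerical
    equilibrium and stability analysis, two-stage bounded least-squares estimation
    from annual victim counts with holdout validation, long-run projections with a
    recovery-year regime switch, and a synthetic-data generator for parameter
    recovery studies. Ships the annual 2010-2023 counts of people treated in
    Mexican medical units by injury intentionality used as the motivating dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
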