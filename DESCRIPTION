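Package: demrecon
Title: Desk-Scale Demographic Estimation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale implementation of the modern demographic
    estimation workflow: abridged and single-year life tables on the 23-group
    age grid, age-specific fertility with terminal-age extension and net
    reproduction, death distribution methods (generalised growth balance,
    synthetic extinct generations and their combination) for vital
    registration completeness, summary-birth-history conversion to under-5
    mortality, sibling-survival adult mortality, a three-stage spatiotemporal
    Gaussian process regression engine with draw-based uncertainty, a
    relational model life table system with flexible standard selection and
    old-age extension, Bayesian cohort-component reconstruction of baseline
    population and net migration from censuses, Sullivan healthy life
    expectancy, expected outcomes given the Socio-demographic Index via a
    cubic-spline ensemble, and a seven-category demographic transition
    taxonomy. A synthetic-world generator produces ground-truth histories and
    noisy multi-source observations (vital registration, censuses, birth and
    sibling histories) against which every estimator is validated.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, splines
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
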