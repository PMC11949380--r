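Package: msexpect
Title: Discrete-Time Multistate Models of Cardiovascular Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An incidence-based discrete-time Markov chain multistate
    (illness-death) toolkit for studying the population burden of
    cardiovascular disease on a quarterly age grid from age 40 to 100.
    Per-step transition probabilities are estimated by multinomial
    logistic regression on person-period panels (age, age squared and
    calendar-period effects, fitted separately by subpopulation) and
    inserted into the Markov transition matrix to obtain lifetime risk,
    mean age at disease onset, disease-free and disease life
    expectancies, and conditional life expectancy for the diseased.
    Includes a register-like synthetic trajectory generator with known
    true parameters, a microsimulation oracle for the matrix
    functionals, direct standardization of transition probabilities
    over the education distribution, reporting utilities for disparity
    gaps and longevity-gain decompositions, and a reproducible
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
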