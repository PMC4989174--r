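Package: pggirs
Title: Evolutionary Dynamics of Public Goods Games with Increasing
    Returns to Scale and Altruistic Punishment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how increasing returns to scale resolve
    the second-order social dilemma in public goods games with altruistic
    punishment. Implements the exact small-mutation-limit stochastic
    analysis of a frequency-dependent Moran process (hypergeometric
    expected payoffs, fixation probabilities, the embedded Markov chain
    over homogeneous states and its stationary distribution) together
    with a fast agent-based simulator of the same process at finite
    mutation rates, parameter-sweep machinery, canned experiment recipes
    and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
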