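Package: decondnet
Title: Attractor-Network Simulations of Fear Memory Updating and Deconditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates fear conditioning, extinction and reconsolidation
    protocols in a fully connected continuous-activity attractor network of
    100 neurons. Memories are stored by a Hebbian outer-product learning rule
    and updated by a mismatch-induced degradation rule driven by the
    discrepancy between a cue and the retrieved network state. The package
    builds the cue patterns (training context, extinction context, tone,
    shock and non-shock clusters), runs seeded multi-session virtual
    experiments with retrieval-trial batteries, models pharmacological
    manipulations as parameter blockade, and reports freezing percentages and
    cluster-averaged synaptic weight matrices as tidy tables with ggplot2
    display helpers.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
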