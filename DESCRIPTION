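Package: sarudango
Title: Individual-Based Simulation of Huddling Cluster Formation in
    Japanese Macaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of huddling ("sarudango") in
    Japanese macaques (Macaca fuscata). Agents on a toroidal grid join and
    leave huddling clusters according to probabilistic threshold rules
    driven by cluster size, group size and ambient temperature. The
    package provides the simulator, a reproducible factorial parameter
    sweep, cluster-size summary metrics, negative-binomial regression of
    the sweep output with collinearity screening and information-criterion
    model selection, and a ranking of simulated temperature-cluster-size
    lines against published empirical site lines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
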