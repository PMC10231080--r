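Package: hollownet
Title: Bipartite Network Analysis of Tree Hollow-Saproxylic Beetle Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative bipartite interaction networks between
    tree-hollow microhabitats and the saproxylic beetles emerging from them.
    Computes network-level indices (connectance, linkage density, interaction
    evenness, H2' specialization, V-ratio), NODF nestedness and Barber
    bipartite modularity with CE null-model significance, temporal beta
    diversity of interactions partitioned into species turnover and rewiring
    components, extinction-curve robustness under random and directed
    microhabitat-loss sequences, generalist-core identification with
    core-degradation threat scenarios, and Hill-number diversity with
    bootstrap confidence intervals and sample-coverage estimation. Includes a
    synthetic community generator that emulates a paired-year, multi-site
    emergence-trap study design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
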