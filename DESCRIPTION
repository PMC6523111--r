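Package: phylocomm
Title: Phylogenetic Community Structure, Trait Conservatism and Stable
    Isotope Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how local species assemblages are put
    together. Computes mean pairwise phylogenetic distance (MPD) and the
    Net Relatedness Index (NRI) against independent-swap null models with
    two-tailed rank tests, under regional or site-specific species pools;
    maps niche traits onto a phylogeny with unordered (Fitch) parsimony
    and squared-change parsimony, counts state transitions, and tests
    trait conservatism by tip permutation; summarises stable-isotope
    delta values (d15N, d13C) by site, feeding group or family with
    one-way ANOVA and Tukey compact letter displays; and ships a
    synthetic-data generator (Yule trees, Brownian traits, filtering and
    competition assembly modes) so the whole pipeline can be exercised
    and calibrated at desk scale.
License: MIT + file LICENSE
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
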