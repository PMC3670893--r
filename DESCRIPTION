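Package: polywasp
Title: Individual-Based Simulation of Sex-Allocation Evolution in
    Polyembryonic Parasitoid Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-generation, individual-based simulation of sex-ratio
    evolution in a polyembryonic, haplodiploid parasitoid wasp with female
    soldier larvae. Females assess host state (parasitism, relatedness and
    sex of prior eggs), accept hosts above an attractiveness threshold, and
    choose egg sex from a heritable per-host-state allocation strategy;
    clones proliferate within hosts with context-dependent survival, mate
    in the natal brood or after dispersal, and pass strategies to offspring
    by parental blending. A genetic-algorithm-style tournament selects an
    evolutionarily stable sex allocation from random starting strategies
    across superparasitism scenarios. Also provides brood-census estimators
    of primary and secondary sex ratios and a synthetic brood-census
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
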