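Package: feassembly
Title: Community Assembly Analysis for Iron Redox Cycling Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the biogeography and assembly mechanisms of
    iron redox cycling bacterial guilds (Fe(II)-oxidizing and
    Fe(III)-reducing bacteria) from 16S amplicon OTU tables. Extracts
    FeOB/FeRB guild communities by genus annotation and best-hit
    similarity, computes alpha diversity (Shannon, Simpson, Good's
    coverage), Bray-Curtis, geographic and standardized environmental
    distance matrices, distance-decay regressions, Mantel, ANOSIM and
    PERMANOVA permutation tests, and an abundance-based null model with
    standardized effect sizes that classifies community assembly as
    deterministic or stochastic. Includes a synthetic metacommunity
    generator mixing species sorting along an environmental gradient
    with dispersal-limited neutral drift, so every statistic has a
    ground-truth parameter-recovery test, plus packaged peatland site
    physicochemistry tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
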