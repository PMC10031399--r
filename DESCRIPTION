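Package: welfareLCA
Title: Life-Cycle-Assessment-Compatible Animal Welfare Cost Metrics for Pig
    Production Systems
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying farm animal welfare on a
    life-cycle-assessment (LCA) footing. Welfare Quality (WQ) principle scores
    from the two stages of a breed-to-finish pig system (sows-and-piglets and
    fattening-pigs) are combined into an overall score by weighting each stage
    by its share of the life-years needed to produce a finished pig, and
    converted into a family of welfare-cost metrics expressed per kg
    deadweight, the LCA functional unit. Life-years per kg deadweight are
    derived from herd productivity records with economic allocation of the
    cull-sow co-product. A thirty-variant metric grid (numeric, WQ
    classification and behaviour-as-benefit cost/benefit transitions crossed
    with three principle weightings) supports robustness analysis via
    tie-corrected Kruskal-Wallis tests, Dunn's post hoc comparisons with Holm
    adjustment, compact letter displays and Spearman rank correlations of
    system rankings. A calibrated synthetic-population generator emulates a
    74-system UK pig sector, including shared breeding/rearing-farm clusters,
    so the full pipeline is testable without restricted farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
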