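Package: reefadapt
Title: Seascape Genomics Indicators of Coral Heat-Stress Adaptation and Reef Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts daily sea-surface-temperature and surface-current fields
    plus coral SNP tables into per-reef indicators of heat stress and dispersal
    -- bleaching-alert frequencies (BAF), probability of heat-stress adaptation
    (PA_HEAT) from pooled logistic genotype-environment models, and inbound /
    outbound connectivity indices (ICI, OCI) from directed least-cost distances
    over a current-driven transition graph -- then relates those indicators to
    coral-cover change with beta-regression mixed models. Includes dbMEM /
    redundancy-analysis validation of the seascape graph against genetic
    structure, and synthetic-seascape generators with recorded ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    glmmTMB,
    pracma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
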